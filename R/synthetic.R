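# Seeded generator for two-sample summary statistics with known truth, so
# selection, harmonization, estimation and diagnostics are testable offline.

#' Configuration for the synthetic summary-statistics generator
#'
#' Describes a two-sample design: J cis variants whose true effects on a
#' continuous exposure (SD units per allele) are drawn from
#' `N(0, gamma_sd^2)`, a binary outcome with a true causal log odds ratio
#' `beta_true` per exposure SD, and optional direct (pleiotropic) variant
#' effects on the outcome violating the exclusion restriction: with
#' probability `pleiotropy_fraction` a variant receives a direct effect
#' `alpha ~ N(pleiotropy_mean, pleiotropy_sd^2)`. Sampling noise follows the
#' standard GWAS approximations: exposure SE `1/sqrt(2 maf (1-maf) n)` and,
#' for the case-control outcome, `1/sqrt(2 maf (1-maf) n_eff v)` with
#' `v = phi (1 - phi)` the case fraction variance factor.
#'
#' Defaults mirror the study conditions this generator emulates: an exposure
#' GWAS of 173,082 individuals and a nephropathy-sized outcome scaled down
#' tenfold (411 cases / 30,854 controls) to keep desk-scale noise realistic
#' but simulations fast; `full_scale = TRUE` restores 4111 / 308,539.
#'
#' @param J Number of variants.
#' @param beta_true True causal log-OR per exposure SD.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case/control counts.
#' @param maf_range Range the minor allele frequency is drawn from, within
#'   (0, 0.5].
#' @param gamma_sd SD of true per-allele exposure effects (SD units).
#' @param pleiotropy_fraction,pleiotropy_mean,pleiotropy_sd Pleiotropy model
#'   (fraction of affected variants; mean and SD of their direct outcome
#'   effects). Zero mean with positive SD gives balanced pleiotropy;
#'   nonzero mean gives directional pleiotropy.
#' @param ld_blocks List of `c(size, within_r2)` pairs; variants are grouped
#'   into consecutive blocks with the stated within-block r-squared and zero
#'   between blocks. Block sizes must sum to at most J; remaining variants
#'   are unlinked.
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param region [gene_region()] the variants are placed in.
#' @param f_target When non-NULL, true exposure effects are resampled until
#'   the implied F-statistic `(gamma/se)^2` reaches this floor, guaranteeing
#'   instrument-grade variants.
#' @param effect_coding `"random"` draws exposure effects symmetric about
#'   zero (arbitrary effect-allele coding); `"exposure_increasing"` codes
#'   every effect allele as the exposure-raising one (takes `|gamma|`).
#'   Directional pleiotropy (`pleiotropy_mean != 0`) is only a coherent
#'   notion under aligned coding: with symmetric coding, re-orienting
#'   variants to a common exposure direction turns a constant direct effect
#'   into a balanced one.
#' @param full_scale Use the unscaled outcome sample sizes.
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(J = 20, beta_true = 0.5, n_exposure = 173082,
                       n_cases = 411, n_controls = 30854,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.05,
                       pleiotropy_fraction = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0, ld_blocks = list(),
                       palindromic_fraction = 0.1,
                       region = gene_region("SYNTH1", "1", 1e6, 2e6),
                       f_target = 10,
                       effect_coding = c("random", "exposure_increasing"),
                       full_scale = FALSE, seed = 1) {
  effect_coding <- match.arg(effect_coding)
  if (full_scale) {
    n_cases <- 4111
    n_controls <- 308539
  }
  stopifnot(J >= 1, n_exposure > 0, n_cases > 0, n_controls > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], gamma_sd > 0,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            pleiotropy_sd >= 0,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  block_sizes <- vapply(ld_blocks, function(b) b[1], numeric(1))
  if (length(block_sizes) > 0 && sum(block_sizes) > J) {
    stop_config("ld_blocks sizes sum to more than J")
  }
  structure(list(J = as.integer(J), beta_true = beta_true,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, maf_range = maf_range,
                 gamma_sd = gamma_sd,
                 pleiotropy_fraction = pleiotropy_fraction,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd, ld_blocks = ld_blocks,
                 palindromic_fraction = palindromic_fraction, region = region,
                 f_target = f_target, effect_coding = effect_coding,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-sample summary-statistics dataset with known truth
#'
#' Generates exposure and outcome association tables in the canonical layout,
#' a block-diagonal LD matrix, and a trait-association table marking grossly
#' pleiotropic variants (|alpha| beyond three pleiotropy SDs, or any nonzero
#' alpha when the pleiotropy SD is zero) as confounder-associated so the
#' confounder screen has true positives to find. Identical (config, seed)
#' reproduce the dataset exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure`, `outcome` (canonical summary-stat
#'   tibbles), `ld` (r-squared matrix), `trait_assoc`, and `truth` (list:
#'   `beta_true`, per-variant `gamma_true` and `alpha`, `outlier_ids`,
#'   `seed`, `config`).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  J <- config$J
  withr::with_seed(config$seed, {
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    gamma_true <- rnorm(J, 0, config$gamma_sd)
    if (!is.null(config$f_target)) {
      weak <- which((gamma_true / se_x)^2 < config$f_target)
      guard <- 0L
      while (length(weak) > 0L && guard < 1000L) {
        gamma_true[weak] <- rnorm(length(weak), 0, config$gamma_sd)
        weak <- weak[(gamma_true[weak] / se_x[weak])^2 < config$f_target]
        guard <- guard + 1L
      }
      if (length(weak) > 0L) {
        stop_config("cannot reach f_target with this gamma_sd / sample size")
      }
    }
    if (config$effect_coding == "exposure_increasing") {
      gamma_true <- abs(gamma_true)
    }
    gamma_hat <- rnorm(J, gamma_true, se_x)

    pleio <- runif(J) < config$pleiotropy_fraction
    alpha <- ifelse(pleio,
                    rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd), 0)
    n_eff <- config$n_cases + config$n_controls
    v <- (config$n_cases / n_eff) * (1 - config$n_cases / n_eff)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_eff * v)
    Gamma_true <- config$beta_true * gamma_true + alpha
    Gamma_hat <- rnorm(J, Gamma_true, se_y)

    pos <- sort(sample(seq(config$region$start, config$region$end), J))
    ids <- sprintf("rs%s%04d", config$region$symbol, seq_len(J))
    pal <- runif(J) < config$palindromic_fraction
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2,
                        byrow = TRUE)
    non_pairs <- matrix(c("A", "G", "A", "C", "G", "A", "C", "A",
                          "T", "G", "T", "C", "G", "T", "C", "T"), ncol = 2,
                        byrow = TRUE)
    pick_pal <- sample.int(4, J, replace = TRUE)
    pick_non <- sample.int(8, J, replace = TRUE)
    ea <- ifelse(pal, pal_pairs[pick_pal, 1], non_pairs[pick_non, 1])
    oa <- ifelse(pal, pal_pairs[pick_pal, 2], non_pairs[pick_non, 2])

    base <- tibble::tibble(
      variant_id = ids, chrom = config$region$chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf)
    exposure <- dplyr::mutate(base, beta = gamma_hat, se = se_x,
                              pval = 2 * pnorm(-abs(gamma_hat / se_x)),
                              n = config$n_exposure)
    outcome <- dplyr::mutate(base, beta = Gamma_hat, se = se_y,
                             pval = 2 * pnorm(-abs(Gamma_hat / se_y)),
                             n = n_eff, n_cases = config$n_cases,
                             n_controls = config$n_controls)

    ld <- diag(1, J)
    dimnames(ld) <- list(ids, ids)
    at <- 1L
    for (b in config$ld_blocks) {
      size <- as.integer(b[1]); r2 <- b[2]
      idx <- seq(at, length.out = size)
      ld[idx, idx] <- r2
      diag(ld)[idx] <- 1
      at <- at + size
    }

    gross <- if (config$pleiotropy_sd > 0) {
      alpha != 0 & abs(alpha) > 3 * config$pleiotropy_sd
    } else {
      alpha != 0
    }
    trait_assoc <- tibble::tibble(
      variant_id = ids[gross],
      trait_name = "synthetic_confounder_trait",
      pval = rep(1e-8, sum(gross)),
      category = rep("confounder", sum(gross)))

    truth <- list(beta_true = config$beta_true, gamma_true = gamma_true,
                  alpha = alpha, outlier_ids = ids[alpha != 0],
                  seed = config$seed, config = config)
    list(exposure = exposure, outcome = outcome, ld = ld,
         trait_assoc = trait_assoc, truth = truth)
  })
}

#' Pair simulated exposure and outcome tables into an instrument set
#'
#' Shortcut for estimator studies that bypasses selection and harmonization:
#' the simulated sources share allele coding by construction, so pairing by
#' row yields a fully harmonized instrument table (action `kept`).
#'
#' @param sim Output of [simulate_dataset()].
#' @return A harmonized instrument tibble.
#' @export
sim_instruments <- function(sim) {
  tibble::tibble(
    variant_id = sim$exposure$variant_id,
    effect_allele = sim$exposure$effect_allele,
    other_allele = sim$exposure$other_allele,
    beta_exposure = sim$exposure$beta,
    se_exposure = sim$exposure$se,
    eaf_exposure = sim$exposure$eaf,
    beta_outcome = sim$outcome$beta,
    se_outcome = sim$outcome$se,
    eaf_outcome = sim$outcome$eaf,
    action = "kept")
}

#' Calibration grid: estimator operating characteristics over replicates
#'
#' Repeatedly simulates datasets from `config` (re-seeded per replicate),
#' runs the requested estimators plus the Cochran's Q and Egger-intercept
#' diagnostics on the paired instruments, and summarises rejection rates at
#' `alpha`, coverage of the true effect, and mean bias per method. This is
#' the engine behind type-I-error, coverage and power checks.
#'
#' @param config A [sim_config()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param methods Estimator names as in [mr_all()].
#' @param alpha Nominal test size (default 0.05).
#' @param n_boot Bootstrap replicates for bootstrap-based methods.
#' @param level Confidence level used for coverage.
#' @return A tibble, one row per method (plus `q_test` and
#'   `egger_intercept` diagnostic rows), with columns `method`, `n_reps`,
#'   `reject_rate`, `coverage`, `mean_estimate`, `mean_bias`.
#' @export
simulate_null_grid <- function(config, n_reps = 200, seed = 1,
                               methods = c("ivw"), alpha = 0.05,
                               n_boot = 200, level = 0.95) {
  res <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    sim <- simulate_dataset(cfg)
    dat <- sim_instruments(sim)
    est <- if (length(methods) > 0L) {
      mr_all(dat, methods, n_boot = n_boot, seed = derive_seed(seed, r),
             level = level)[c("method", "beta", "se", "pval", "ci_low", "ci_high")]
    } else {
      NULL
    }
    diag_rows <- dplyr::bind_rows(
      if (nrow(dat) >= 2L) {
        qr <- cochran_q(dat)
        tibble::tibble(method = "q_test", beta = NA_real_, se = NA_real_,
                       pval = qr$q_pval, ci_low = NA_real_, ci_high = NA_real_)
      },
      if (nrow(dat) >= 3L) {
        er <- egger_intercept_test(dat)
        tibble::tibble(method = "egger_intercept", beta = er$egger_intercept,
                       se = er$egger_intercept_se,
                       pval = er$egger_intercept_pval,
                       ci_low = NA_real_, ci_high = NA_real_)
      })
    dplyr::bind_rows(est, diag_rows)
  })
  all <- dplyr::bind_rows(res)
  truth <- config$beta_true
  all |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      reject_rate = mean(.data$pval < alpha),
      coverage = mean(log(.data$ci_low) <= truth & truth <= log(.data$ci_high)),
      mean_estimate = mean(.data$beta),
      mean_bias = mean(.data$beta - truth),
      .groups = "drop")
}
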