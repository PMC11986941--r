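# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(((beta_outcome - beta_ref * beta_exposure) / se_outcome)^2)` with
#' J - 1 degrees of freedom and an upper-tail chi-square p-value. Under
#' homogeneity (all instruments estimating the same causal effect) Q is
#' approximately chi-square distributed; small p-values indicate
#' heterogeneity across per-SNP estimates.
#'
#' @param data Harmonized instrument tibble (J >= 2).
#' @param beta_ref Reference slope; defaults to the fixed-effect IVW estimate.
#' @return A one-row tibble with `q`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(data, beta_ref = NULL) {
  check_instruments(data, 2L, "cochran_q")
  if (is.null(beta_ref)) {
    beta_ref <- ivw_core(data$beta_exposure, data$beta_outcome,
                         data$se_outcome)$beta
  }
  q <- sum(((data$beta_outcome - beta_ref * data$beta_exposure) /
              data$se_outcome)^2)
  df <- nrow(data) - 1L
  tibble::tibble(q = q, q_df = df, q_pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept of the MR-Egger regression with its standard error
#' and t-test (J - 2 df). An intercept p-value above 0.05 is conventionally
#' read as no evidence of directional horizontal pleiotropy.
#'
#' @param data Harmonized instrument tibble (J >= 3).
#' @return A one-row tibble with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, and the conventional `verdict` string.
#' @export
egger_intercept_test <- function(data) {
  est <- mr_egger(data)
  tibble::tibble(
    egger_intercept = est$egger_intercept,
    egger_intercept_se = est$egger_intercept_se,
    egger_intercept_pval = est$egger_intercept_pval,
    verdict = ifelse(est$egger_intercept_pval > 0.05,
                     "no horizontal pleiotropy", "horizontal pleiotropy")
  )
}

# Leave-one-out fixed-effect IVW slopes, vectorized: drop SNP j from the sums.
loo_slopes <- function(g, G, sy) {
  w <- 1 / sy^2
  num <- sum(w * g * G) - w * g * G
  den <- sum(w * g^2) - w * g^2
  num / den
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection and correction of pleiotropic outliers.
#' (a) Global test: the observed residual sum of squares
#' `RSS = sum((beta_outcome_j - beta_loo_j * beta_exposure_j)^2)` — each SNP's
#' residual taken against the leave-one-out IVW slope — is compared with
#' `n_sim` simulated RSS values in which exposure and outcome effects are
#' redrawn from their sampling distributions under the no-pleiotropy model
#' and the leave-one-out slopes recomputed on the simulated data; the global
#' p is `(1 + #(RSS* >= RSS)) / (1 + n_sim)`. (b) Outlier test: each SNP's
#' observed squared residual is ranked within its own simulated distribution
#' and the p-value Bonferroni-multiplied by J; adjusted p < `sig` flags an
#' outlier. (c) Distortion test (only when outliers are found): the change in
#' the IVW estimate after removing the outliers is compared against removals
#' of random subsets of the same size. The corrected estimate is IVW on the
#' non-outliers.
#'
#' @param data Harmonized instrument tibble (J >= 4).
#' @param n_sim Number of simulations (default 1000; < 100 warns).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param sig Outlier significance threshold on the Bonferroni-adjusted
#'   p-value (default 0.05).
#' @return A list of class `mr_presso` with `global_pval`, `outliers` (tibble
#'   of flagged variants with adjusted p), `outlier_pvals` (all J adjusted
#'   p-values), `distortion_pval` (NA when no outliers), and `corrected` (an
#'   `mr_estimate` row on the non-outliers, NULL when no outliers or too few
#'   remain).
#' @export
mr_presso <- function(data, n_sim = 1000, seed = 1, sig = 0.05) {
  check_instruments(data, 4L, "mr_presso")
  if (n_sim < 100) warn("mr_presso: n_sim < 100 gives a very coarse p-value")
  J <- nrow(data)
  g <- data$beta_exposure; sx <- data$se_exposure
  G <- data$beta_outcome; sy <- data$se_outcome
  w <- 1 / sy^2

  beta_loo <- loo_slopes(g, G, sy)
  res_obs <- G - beta_loo * g
  rss_obs <- sum(res_obs^2)

  sim <- withr::with_seed(seed, {
    gs <- matrix(rnorm(J * n_sim, g, sx), nrow = J)
    Gs <- matrix(rnorm(J * n_sim, beta_loo * g, sy), nrow = J)
    num_tot <- colSums(w * gs * Gs)
    den_tot <- colSums(w * gs^2)
    beta_loo_s <- (matrix(num_tot, J, n_sim, byrow = TRUE) - w * gs * Gs) /
      (matrix(den_tot, J, n_sim, byrow = TRUE) - w * gs^2)
    res_s <- Gs - beta_loo_s * gs
    list(rss = colSums(res_s^2), res2 = res_s^2)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  p_snp <- (1 + rowSums(sim$res2 >= res_obs^2)) / (1 + n_sim)
  p_adj <- pmin(1, p_snp * J)
  out_idx <- which(p_adj < sig)

  outliers <- tibble::tibble(
    variant_id = if ("variant_id" %in% names(data))
      data$variant_id[out_idx] else as.character(out_idx),
    p_adjusted = p_adj[out_idx]
  )

  distortion_pval <- NA_real_
  corrected <- NULL
  if (length(out_idx) > 0L && J - length(out_idx) >= 2L) {
    keep <- setdiff(seq_len(J), out_idx)
    corrected <- mr_ivw(data[keep, , drop = FALSE])
    beta_all <- ivw_core(g, G, sy)$beta
    d_obs <- corrected$beta - beta_all
    d_null <- withr::with_seed(derive_seed(seed, 101L), {
      vapply(seq_len(n_sim), function(s) {
        drop_s <- sample.int(J, length(out_idx))
        ivw_core(g[-drop_s], G[-drop_s], sy[-drop_s])$beta - beta_all
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
  }

  structure(list(global_pval = global_pval, outliers = outliers,
                 outlier_pvals = tibble::tibble(
                   variant_id = if ("variant_id" %in% names(data))
                     data$variant_id else as.character(seq_len(J)),
                   p_adjusted = p_adj),
                 distortion_pval = distortion_pval, corrected = corrected,
                 n_sim = n_sim, seed = seed, sig = sig),
            class = "mr_presso")
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate J times, each time omitting one instrument,
#' plus an all-SNP row. Rows whose confidence interval excludes the all-SNP
#' point estimate are flagged as influential.
#'
#' @param data Harmonized instrument tibble (J >= 3).
#' @param model IVW flavour passed to [mr_ivw()].
#' @param level Confidence level.
#' @return A tibble with J + 1 rows: `omitted` (variant id or `"none"`),
#'   the `mr_estimate` columns, and `influential`.
#' @export
leave_one_out <- function(data, model = "random_multiplicative", level = 0.95) {
  check_instruments(data, 3L, "leave_one_out")
  J <- nrow(data)
  ids <- if ("variant_id" %in% names(data)) data$variant_id else as.character(seq_len(J))
  full <- mr_ivw(data, model, level)
  rows <- purrr::map(seq_len(J), function(j) {
    est <- mr_ivw(data[-j, , drop = FALSE], model, level)
    dplyr::mutate(est, omitted = ids[j], .before = 1L)
  })
  out <- dplyr::bind_rows(c(rows, list(dplyr::mutate(full, omitted = "none",
                                                     .before = 1L))))
  dplyr::mutate(out,
                influential = .data$omitted != "none" &
                  (log(.data$ci_low) > full$beta | log(.data$ci_high) < full$beta))
}

#' Full sensitivity battery for one instrument set
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO and the
#' leave-one-out table into one report. Components whose minimum instrument
#' count exceeds J are returned as NA/NULL rather than erroring.
#'
#' @param data Harmonized instrument tibble.
#' @param n_sim MR-PRESSO simulations.
#' @param seed Integer seed for MR-PRESSO.
#' @param sig MR-PRESSO outlier threshold.
#' @return A list of class `mr_sensitivity` with elements `summary` (one-row
#'   tibble: Q, Egger intercept, MR-PRESSO global/distortion), `presso`, and
#'   `loo`.
#' @export
sensitivity_report <- function(data, n_sim = 1000, seed = 1, sig = 0.05) {
  J <- nrow(data)
  qrow <- if (J >= 2L) cochran_q(data) else
    tibble::tibble(q = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
  erow <- if (J >= 3L) egger_intercept_test(data)[1:3] else
    tibble::tibble(egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                   egger_intercept_pval = NA_real_)
  presso <- if (J >= 4L) mr_presso(data, n_sim, seed, sig) else NULL
  loo <- if (J >= 3L) leave_one_out(data) else NULL

  summary <- dplyr::bind_cols(
    tibble::tibble(n_snp = J), qrow, erow,
    tibble::tibble(
      presso_global_pval = if (is.null(presso)) NA_real_ else presso$global_pval,
      presso_n_outliers = if (is.null(presso)) NA_integer_ else nrow(presso$outliers),
      presso_distortion_pval = if (is.null(presso)) NA_real_ else presso$distortion_pval
    ))
  structure(list(summary = summary, presso = presso, loo = loo),
            class = "mr_sensitivity")
}
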