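# End-to-end orchestration over target x outcome pairs, including the
# positive control and the heterogeneity-triggered stricter-LD rerun.

#' Analysis configuration for a drug-target MR study
#'
#' @param selection A [selection_params()] object (primary LD threshold lives
#'   in `selection$r2_max`).
#' @param r2_strict Stricter clumping threshold used when a pair shows
#'   heterogeneity or directional pleiotropy (default 0.1; must be below
#'   `selection$r2_max`).
#' @param methods Estimator battery per pair (see [mr_all()]).
#' @param direction Exposure orientation (see [orient_exposure()]); the
#'   default `per_sd_decrease` reports drug-mimicking (inhibitor) effects.
#' @param palindrome_window Passed to [harmonize()].
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param n_sim MR-PRESSO simulations.
#' @param seed Master seed; every stochastic component receives a sub-seed
#'   derived from it, so a study is a pure function of (inputs, config).
#' @param level Confidence level.
#' @param rerun_alpha Trigger threshold: a pair is rerun at `r2_strict` when
#'   its Cochran's Q p-value or Egger intercept p-value is at or below this
#'   (default 0.05).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(selection = selection_params(), r2_strict = 0.1,
                            methods = c("ivw", "egger", "weighted_median",
                                        "simple_mode", "weighted_mode"),
                            direction = "per_sd_decrease",
                            palindrome_window = 0.08, n_boot = 1000,
                            n_sim = 1000, seed = 1, level = 0.95,
                            rerun_alpha = 0.05) {
  if (r2_strict >= selection$r2_max) {
    stop_config("r2_strict must be below selection$r2_max")
  }
  structure(list(selection = selection, r2_strict = r2_strict,
                 methods = methods, direction = direction,
                 palindrome_window = palindrome_window, n_boot = n_boot,
                 n_sim = n_sim, seed = as.integer(seed), level = level,
                 rerun_alpha = rerun_alpha),
            class = "analysis_config")
}

# One selection -> harmonize -> estimate -> diagnose sweep at a given r2.
analyze_once <- function(exposure, outcome, region, ld, trait_assoc, config,
                         r2_max, seed) {
  params <- config$selection
  params$r2_max <- r2_max
  sel <- suppressWarnings(
    select_instruments(exposure, region, ld, trait_assoc, params))
  sel_audit <- attr(sel, "audit")
  if (nrow(sel) == 0L) {
    return(list(status = "no_instruments", selection_audit = sel_audit))
  }
  harm <- harmonize(sel, outcome, config$palindrome_window)
  harm_audit <- attr(harm, "audit")
  if (nrow(harm) == 0L) {
    return(list(status = "no_instruments", selection_audit = sel_audit,
                harmonization_audit = harm_audit))
  }
  dat <- orient_exposure(harm, config$direction)
  J <- nrow(dat)

  methods <- config$methods
  if (J < 3L) methods <- intersect(methods, c("wald", "ivw", "ivw_fixed"))
  est <- mr_all(dat, methods, n_boot = config$n_boot, seed = seed,
                level = config$level)
  sens <- sensitivity_report(dat, n_sim = config$n_sim,
                             seed = derive_seed(seed, 7L))
  list(status = if (J < 3L) "limited_instruments" else "ok",
       instruments = dat, estimates = est, sensitivity = sens,
       selection_audit = sel_audit, harmonization_audit = harm_audit)
}

#' Analyse one target-outcome pair
#'
#' Runs instrument selection, harmonization, the estimator battery and the
#' full sensitivity report for one drug-target gene against one outcome.
#' When the Cochran's Q p-value or the Egger intercept p-value falls at or
#' below `config$rerun_alpha`, the pair is automatically re-analysed with the
#' stricter clumping threshold `config$r2_strict` and the rerun appended
#' (flagged in the `rerun` column), mirroring the practice of tightening the
#' LD threshold to clear heterogeneity. Pairs with no surviving instrument
#' are returned as not-estimable placeholders; pairs with one or two
#' instruments report Wald/IVW only, with a warning.
#'
#' @param exposure Exposure summary-statistics tibble.
#' @param outcome Outcome summary-statistics tibble.
#' @param region [gene_region()] for the target.
#' @param ld LD r-squared matrix covering the exposure variants.
#' @param trait_assoc Trait-association tibble (or NULL to skip the screen).
#' @param config An [analysis_config()].
#' @param target_name,outcome_name Labels for the report (target defaults to
#'   the region symbol).
#' @return A list of class `mr_pair`: `estimates` (tibble over original and
#'   any rerun analysis), `sensitivity` (one row per analysis),
#'   `analyses` (full per-analysis detail incl. instruments, audits, PRESSO,
#'   leave-one-out), `status`, and the labels.
#' @export
run_pair <- function(exposure, outcome, region, ld, trait_assoc = NULL,
                     config = analysis_config(),
                     target_name = region$symbol, outcome_name = "outcome") {
  seed0 <- derive_seed(config$seed, sum(utf8ToInt(paste0(target_name, "|",
                                                         outcome_name))))
  primary <- analyze_once(exposure, outcome, region, ld, trait_assoc, config,
                          config$selection$r2_max, seed0)
  analyses <- list(primary = primary)

  decorate <- function(res, r2, rerun) {
    if (is.null(res$estimates)) return(NULL)
    dplyr::mutate(res$estimates, target = target_name, outcome = outcome_name,
                  r2_max = r2, rerun = rerun, .before = 1L)
  }
  sens_row <- function(res, r2, rerun) {
    if (is.null(res$sensitivity)) return(NULL)
    dplyr::mutate(res$sensitivity$summary, target = target_name,
                  outcome = outcome_name, r2_max = r2, rerun = rerun,
                  .before = 1L)
  }

  est <- decorate(primary, config$selection$r2_max, FALSE)
  sens <- sens_row(primary, config$selection$r2_max, FALSE)

  triggered <- FALSE
  if (!is.null(sens)) {
    qp <- sens$q_pval
    ep <- sens$egger_intercept_pval
    triggered <- (!is.na(qp) && qp <= config$rerun_alpha) ||
      (!is.na(ep) && ep <= config$rerun_alpha)
  }
  if (triggered) {
    rerun <- analyze_once(exposure, outcome, region, ld, trait_assoc, config,
                          config$r2_strict, derive_seed(seed0, 1L))
    analyses$rerun <- rerun
    est <- dplyr::bind_rows(est, decorate(rerun, config$r2_strict, TRUE))
    sens <- dplyr::bind_rows(sens, sens_row(rerun, config$r2_strict, TRUE))
  }

  if (primary$status == "limited_instruments") {
    warn(paste0(target_name, " vs ", outcome_name,
                ": fewer than 3 instruments; only Wald/IVW reported"))
  }
  if (is.null(est)) {
    est <- dplyr::mutate(empty_estimates()[0, ])
    est <- tibble::add_row(est, target = target_name, outcome = outcome_name,
                           method = "not_estimable", n_snp = 0L,
                           r2_max = config$selection$r2_max, rerun = FALSE)
    sens <- empty_sensitivity()
  }

  structure(list(target = target_name, outcome = outcome_name,
                 estimates = est, sensitivity = sens, analyses = analyses,
                 status = primary$status, rerun_triggered = triggered,
                 seeds = list(pair_seed = seed0),
                 parameters = config[c("r2_strict", "direction",
                                       "palindrome_window", "n_boot", "n_sim",
                                       "level", "rerun_alpha")]),
            class = "mr_pair")
}

#' Run a full drug-target MR study
#'
#' Iterates all target x outcome pairs. When a positive-control outcome is
#' named it is analysed first for every target, and targets whose
#' positive-control IVW confidence interval includes 1 are flagged as control
#' failures (the analysis still proceeds). Results are consolidated into
#' estimate and sensitivity tables plus a forest-layout table (one row per
#' target x outcome x method); when `out_dir` is given the consolidated
#' report is written via [write_mr_report()] together with `forest.tsv`.
#' A Bonferroni-adjusted p-value column across target-outcome pairs is
#' emitted for transparency but plays no part in any verdict.
#'
#' @param targets A list; each element a list with `region` ([gene_region()]),
#'   `exposure` (tibble or file path), and `ld` (matrix or file path).
#' @param outcomes Named list of outcome tibbles or file paths.
#' @param trait_assoc Trait-association tibble, file path, or NULL.
#' @param config An [analysis_config()].
#' @param positive_control Name of the outcome to treat as positive control
#'   (must appear in `outcomes`), or NULL.
#' @param out_dir Output directory for the written report, or NULL to skip
#'   writing.
#' @return A list of class `mr_study`: `estimates`, `sensitivity`, `forest`,
#'   `control` (per-target control verdicts), `pairs` (all `mr_pair`
#'   objects), `parameters`, `seeds`.
#' @export
run_study <- function(targets, outcomes, trait_assoc = NULL,
                      config = analysis_config(), positive_control = NULL,
                      out_dir = NULL) {
  if (length(targets) == 0L || length(outcomes) == 0L) {
    stop_config("at least one target and one outcome are required")
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop_config("outcomes must be a named list")
  }
  if (!is.null(positive_control) && !positive_control %in% names(outcomes)) {
    stop_config("positive_control must name an element of outcomes")
  }
  if (is.character(trait_assoc)) trait_assoc <- read_trait_associations(trait_assoc)

  load_target <- function(t) {
    if (is.character(t$exposure)) t$exposure <- read_summary_stats(t$exposure)
    if (is.character(t$ld)) t$ld <- read_ld_matrix(t$ld)
    t
  }
  targets <- purrr::map(targets, load_target)
  outcomes <- purrr::map(outcomes, function(o) {
    if (is.character(o)) read_summary_stats(o, trait_type = "binary") else o
  })

  outcome_order <- c(intersect(positive_control, names(outcomes)),
                     setdiff(names(outcomes), positive_control))
  pairs <- list()
  control <- list()
  for (t in targets) {
    for (oname in outcome_order) {
      pair <- tryCatch(
        run_pair(t$exposure, outcomes[[oname]], t$region, t$ld, trait_assoc,
                 config, target_name = t$region$symbol, outcome_name = oname),
        error = function(e) {
          warn(paste0("pair ", t$region$symbol, " vs ", oname, " failed: ",
                      conditionMessage(e)))
          NULL
        })
      if (is.null(pair)) next
      pairs[[paste(t$region$symbol, oname, sep = ".")]] <- pair
      if (!is.null(positive_control) && oname == positive_control) {
        ivw <- dplyr::filter(pair$estimates, .data$method %in%
                               c("ivw_random", "ivw_fixed", "wald"),
                             !.data$rerun)
        passed <- nrow(ivw) > 0 &&
          (ivw$ci_low[1] > 1 || ivw$ci_high[1] < 1)
        control[[t$region$symbol]] <- tibble::tibble(
          target = t$region$symbol, control_outcome = oname,
          control_pass = passed)
        if (!passed) {
          warn(paste0("positive-control failure for ", t$region$symbol,
                      ": IVW CI includes 1"))
        }
      }
    }
  }

  estimates <- dplyr::bind_rows(purrr::map(pairs, "estimates"))
  sensitivity <- dplyr::bind_rows(purrr::map(pairs, "sensitivity"))
  if (nrow(estimates) > 0L) {
    n_pairs <- dplyr::n_distinct(paste(estimates$target, estimates$outcome))
    estimates <- dplyr::mutate(estimates,
                               pval_bonferroni = pmin(1, .data$pval * n_pairs))
  }
  forest <- dplyr::select(estimates, dplyr::any_of(c(
    "outcome", "target", "method", "n_snp", "pval", "or", "ci_low", "ci_high",
    "r2_max", "rerun")))

  study <- structure(list(estimates = estimates, sensitivity = sensitivity,
                          forest = forest,
                          control = dplyr::bind_rows(control), pairs = pairs,
                          parameters = config[setdiff(names(config), "selection")],
                          seeds = list(seed = config$seed)),
                     class = "mr_study")
  if (!is.null(out_dir)) {
    write_mr_report(study, out_dir)
    forest_disp <- dplyr::mutate(forest,
                                 dplyr::across(dplyr::where(is.numeric),
                                               ~ signif(.x, 4)))
    readr::write_tsv(forest_disp, file.path(out_dir, "forest.tsv"),
                     progress = FALSE)
  }
  study
}
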