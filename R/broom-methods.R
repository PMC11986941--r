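# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a target-outcome pair analysis
#'
#' @param x An `mr_pair` object.
#' @param ... Unused.
#' @return The estimates tibble: one row per method (and per rerun, when the
#'   stricter-LD rerun was triggered).
#' @export
tidy.mr_pair <- function(x, ...) x$estimates

#' One-row summary of a target-outcome pair
#'
#' @param x An `mr_pair` object.
#' @param ... Unused.
#' @return A one-row tibble: labels, instrument count, primary IVW estimate,
#'   heterogeneity / pleiotropy / MR-PRESSO p-values and the rerun flag.
#' @export
glance.mr_pair <- function(x, ...) {
  ivw <- dplyr::filter(x$estimates,
                       .data$method %in% c("ivw_random", "ivw_fixed", "wald"),
                       !.data$rerun)
  sens <- dplyr::filter(x$sensitivity, !.data$rerun)
  tibble::tibble(
    target = x$target, outcome = x$outcome, status = x$status,
    n_snp = if (nrow(ivw) > 0) ivw$n_snp[1] else 0L,
    beta_ivw = if (nrow(ivw) > 0) ivw$beta[1] else NA_real_,
    or_ivw = if (nrow(ivw) > 0) ivw$or[1] else NA_real_,
    pval_ivw = if (nrow(ivw) > 0) ivw$pval[1] else NA_real_,
    q_pval = if (nrow(sens) > 0) sens$q_pval[1] else NA_real_,
    egger_intercept_pval = if (nrow(sens) > 0) sens$egger_intercept_pval[1] else NA_real_,
    presso_global_pval = if (nrow(sens) > 0) sens$presso_global_pval[1] else NA_real_,
    rerun_triggered = x$rerun_triggered)
}

#' Tidy a full study
#'
#' @param x An `mr_study` object.
#' @param ... Unused.
#' @return The consolidated estimates tibble.
#' @export
tidy.mr_study <- function(x, ...) x$estimates

#' Per-pair summary of a full study
#'
#' @param x An `mr_study` object.
#' @param ... Unused.
#' @return A tibble with one row per target-outcome pair (see
#'   [glance.mr_pair()]).
#' @export
glance.mr_study <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$pairs, glance))
}

#' Tidy a sensitivity report
#'
#' @param x An `mr_sensitivity` object.
#' @param ... Unused.
#' @return The leave-one-out table (NULL-safe: zero rows when unavailable).
#' @export
tidy.mr_sensitivity <- function(x, ...) {
  x$loo %||% tibble::tibble()
}

#' One-row summary of a sensitivity report
#'
#' @param x An `mr_sensitivity` object.
#' @param ... Unused.
#' @return The summary row (Q, Egger intercept, MR-PRESSO).
#' @export
glance.mr_sensitivity <- function(x, ...) x$summary

#' Forest plot of study estimates
#'
#' Odds ratios with confidence intervals, one row per target-outcome-method,
#' on a log-scaled axis with a reference line at OR = 1. Rerun rows (stricter
#' LD threshold) are marked.
#'
#' @param object An `mr_study` or `mr_pair` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_study <- function(object, ...) {
  dat <- dplyr::filter(object$estimates, !is.na(.data$or))
  dat <- dplyr::mutate(dat,
                       label = paste0(.data$target,
                                      ifelse(.data$rerun, "*", ""),
                                      " | ", .data$method))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$outcome), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Odds ratio (95% CI), log scale", y = NULL,
                  caption = "* stricter LD threshold rerun") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mr_study
#' @export
autoplot.mr_pair <- function(object, ...) {
  study_like <- list(estimates = object$estimates)
  class(study_like) <- "mr_study"
  autoplot.mr_study(study_like)
}

#' Leave-one-out influence plot
#'
#' Plots the IVW estimate obtained when each instrument is omitted in turn,
#' against the all-SNP estimate.
#'
#' @param loo A leave-one-out table from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  full <- dplyr::filter(loo, .data$omitted == "none")
  ggplot2::ggplot(dplyr::filter(loo, .data$omitted != "none"),
                  ggplot2::aes(x = .data$beta, y = .data$omitted)) +
    ggplot2::geom_vline(xintercept = full$beta, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                         xmax = .data$beta + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log OR per exposure unit (omitting each variant)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
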