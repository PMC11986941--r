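# Causal-effect estimators for a harmonized instrument set. All exported
# estimators take a tibble with columns beta_exposure, se_exposure,
# beta_outcome, se_outcome and return a one-row tibble (class "mr_estimate")
# with method, n_snp, beta, se, pval, or, ci_low, ci_high. Every estimator is
# invariant to SNP order and to jointly negating (beta_exposure,
# beta_outcome) of any SNP (allele recoding).

mr_estimate_row <- function(method, n_snp, beta, se, pval, level = 0.95, ...) {
  ci <- to_odds_ratio(beta, se, level)
  out <- tibble::tibble(method = method, n_snp = as.integer(n_snp),
                        beta = beta, se = se, pval = pval,
                        or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high, ...)
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Convert a log odds ratio and its standard error to OR with CI
#'
#' @param beta Log odds ratio.
#' @param se Standard error of `beta` (> 0, or 0 for a degenerate point CI).
#' @param level Confidence level (default 0.95).
#' @return A list with `or`, `ci_low`, `ci_high`; `or = exp(beta)` and the
#'   interval is `exp(beta -/+ z * se)`.
#' @examples
#' to_odds_ratio(log(2), 0.1)
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  if (any(!is.na(se) & se < 0)) stop_input("to_odds_ratio: se must be >= 0")
  z <- qnorm(1 - (1 - level) / 2)
  list(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate beta = beta_outcome / beta_exposure with the
#' first-order standard error se_outcome / |beta_exposure| and a two-sided
#' normal p-value. Building block of all multi-SNP estimators.
#'
#' @param data A one-row harmonized instrument tibble (rows beyond the first
#'   are an error; `beta_exposure` must be nonzero).
#' @param level Confidence level for the OR interval.
#' @return A one-row `mr_estimate` tibble.
#' @export
mr_wald_ratio <- function(data, level = 0.95) {
  check_instruments(data, 1L, "mr_wald_ratio")
  if (nrow(data) != 1L) stop_input("mr_wald_ratio expects exactly one instrument")
  if (data$beta_exposure == 0) {
    stop_input("degenerate instrument: beta_exposure is zero")
  }
  beta <- data$beta_outcome / data$beta_exposure
  se <- data$se_outcome / abs(data$beta_exposure)
  mr_estimate_row("wald", 1L, beta, se, 2 * pnorm(-abs(beta / se)), level)
}

# Core IVW sums; shared by estimators and diagnostics.
ivw_core <- function(g, G, sy) {
  w <- 1 / sy^2
  denom <- sum(w * g^2)
  beta <- sum(w * g * G) / denom
  q <- sum(w * (G - beta * g)^2)
  list(beta = beta, se_fixed = sqrt(1 / denom), q = q)
}

#' Inverse-variance-weighted estimate
#'
#' The IVW estimate is the weighted regression of outcome effects on exposure
#' effects through the origin with weights `1 / se_outcome^2`:
#' `beta = sum(w g G) / sum(w g^2)`. The fixed-effect standard error is
#' `sum(w g^2)^(-1/2)`; the multiplicative random-effects model (the default,
#' and the common default in two-sample MR software) inflates it by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's heterogeneity statistic
#' at the fixed-effect slope. P-values are two-sided normal. A single
#' instrument delegates to [mr_wald_ratio()].
#'
#' @param data Harmonized instrument tibble (J >= 1).
#' @param model `"random_multiplicative"` (default) or `"fixed"`.
#' @param level Confidence level.
#' @return A one-row `mr_estimate` tibble; method is `"ivw_fixed"` or
#'   `"ivw_random"`.
#' @export
mr_ivw <- function(data, model = c("random_multiplicative", "fixed"),
                   level = 0.95) {
  model <- match.arg(model)
  check_instruments(data, 1L, "mr_ivw")
  if (nrow(data) == 1L) return(mr_wald_ratio(data, level))
  fit <- ivw_core(data$beta_exposure, data$beta_outcome, data$se_outcome)
  J <- nrow(data)
  if (model == "fixed") {
    se <- fit$se_fixed
    method <- "ivw_fixed"
  } else {
    se <- fit$se_fixed * max(1, sqrt(fit$q / (J - 1)))
    method <- "ivw_random"
  }
  mr_estimate_row(method, J, fit$beta, se, 2 * pnorm(-abs(fit$beta / se)), level)
}

# Weighted linear regression with intercept via closed-form normal equations;
# SEs inflated by the residual scale when it exceeds 1 (multiplicative
# overdispersion, never deflated).
egger_core <- function(g, G, sy) {
  s <- ifelse(g < 0, -1, 1)     # orient so every exposure effect is positive
  x <- g * s
  y <- G * s
  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swxx * swy - swx * swxy) / d
  J <- length(g)
  rss <- sum(w * (y - intercept - slope * x)^2)
  phi <- max(1, sqrt(rss / (J - 2)))
  se_slope <- sqrt(sw / d) * phi
  se_intercept <- sqrt(swxx / d) * phi
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept, df = J - 2)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an unconstrained
#' intercept, after orienting every SNP so its exposure effect is positive
#' (a joint sign flip that leaves the slope invariant). The slope is the
#' pleiotropy-adjusted causal estimate; a nonzero intercept indicates
#' directional horizontal pleiotropy. Standard errors carry a multiplicative
#' overdispersion factor `max(1, residual SD)` and p-values use the t
#' distribution with J - 2 degrees of freedom.
#'
#' @param data Harmonized instrument tibble (J >= 3).
#' @param level Confidence level.
#' @return A one-row `mr_estimate` tibble with extra columns
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`.
#' @export
mr_egger <- function(data, level = 0.95) {
  check_instruments(data, 3L, "mr_egger")
  fit <- egger_core(data$beta_exposure, data$beta_outcome, data$se_outcome)
  p_slope <- 2 * pt(-abs(fit$slope / fit$se_slope), df = fit$df)
  p_int <- 2 * pt(-abs(fit$intercept / fit$se_intercept), df = fit$df)
  mr_estimate_row("egger", nrow(data), fit$slope, fit$se_slope, p_slope, level,
                  egger_intercept = fit$intercept,
                  egger_intercept_se = fit$se_intercept,
                  egger_intercept_pval = p_int)
}

# Weighted median of ratio estimates by linear interpolation of the
# cumulative-weight midpoints at probability 0.5.
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(b[1])
  n <- length(b)
  if (p[n] <= 0.5) return(b[n])
  approx(p, b, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by median and mode estimators: resample
# exposure and outcome effects from their sampling distributions, recompute
# the point estimate, take the SD across replicates.
bootstrap_se <- function(data, point_fun, n_boot, seed) {
  if (n_boot < 2) return(NA_real_)   # n_boot = 0 requests the point estimate only
  J <- nrow(data)
  withr::with_seed(seed, {
    g <- matrix(rnorm(J * n_boot, data$beta_exposure, data$se_exposure), nrow = J)
    G <- matrix(rnorm(J * n_boot, data$beta_outcome, data$se_outcome), nrow = J)
    est <- vapply(seq_len(n_boot),
                  function(i) point_fun(g[, i], G[, i], data$se_outcome),
                  numeric(1))
    sd(est)
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the weight-0.5 point of their
#' cumulative weight distribution (linear interpolation between cumulative
#' midpoints), with first-order weights `beta_exposure^2 / se_outcome^2`.
#' Consistent when at least half the instrument weight comes from valid
#' instruments. The standard error is a seeded parametric bootstrap:
#' exposure and outcome effects are resampled from normal sampling
#' distributions and the estimate recomputed.
#'
#' @param data Harmonized instrument tibble (J >= 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @param level Confidence level.
#' @return A one-row `mr_estimate` tibble.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1, level = 0.95) {
  check_instruments(data, 3L, "mr_weighted_median")
  point_fun <- function(g, G, sy) {
    weighted_median_point(G / g, g^2 / sy^2)
  }
  beta <- point_fun(data$beta_exposure, data$beta_outcome, data$se_outcome)
  se <- bootstrap_se(data, point_fun, n_boot, seed)
  pval <- if (is.na(se) || se > 0) 2 * pnorm(-abs(beta / se)) else 1e-300
  mr_estimate_row("weighted_median", nrow(data), beta, se, pval, level)
}

# Mode of the kernel-smoothed ratio distribution on a 512-point grid.
mode_point <- function(ratios, weights, phi) {
  spread <- c(sd(ratios), IQR(ratios) / 1.349)
  spread <- spread[is.finite(spread) & spread > 0]
  if (length(spread) == 0L) return(ratios[1])  # all ratios identical
  h <- phi * 0.9 * min(spread) * length(ratios)^(-1/5)
  d <- suppressWarnings(density(ratios, weights = weights / sum(weights),
                                bw = h, kernel = "gaussian", n = 512,
                                from = min(ratios) - 3 * h,
                                to = max(ratios) + 3 * h))
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple and weighted)
#'
#' Estimates the causal effect as the mode of the kernel-smoothed density of
#' the per-SNP Wald ratios, using a Gaussian kernel with bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)` evaluated on a 512-point
#' grid spanning `[min - 3h, max + 3h]`. The simple mode weighs every ratio
#' equally; the weighted mode weighs each by `beta_exposure^2 /
#' se_outcome^2`. Consistent when the largest group of instruments sharing a
#' ratio is valid (ZEMPA). SE by the same seeded parametric bootstrap as the
#' weighted median. When all ratios coincide the bandwidth is degenerate and
#' the common ratio is returned directly.
#'
#' @param data Harmonized instrument tibble (J >= 3).
#' @param weighted `TRUE` for the weighted mode, `FALSE` for the simple mode.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A one-row `mr_estimate` tibble; method is `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(data, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1,
                    level = 0.95) {
  check_instruments(data, 3L, "mr_mode")
  point_fun <- function(g, G, sy) {
    w <- if (weighted) g^2 / sy^2 else rep(1, length(g))
    mode_point(G / g, w, phi)
  }
  beta <- point_fun(data$beta_exposure, data$beta_outcome, data$se_outcome)
  se <- bootstrap_se(data, point_fun, n_boot, seed)
  pval <- if (is.na(se) || se > 0) 2 * pnorm(-abs(beta / se)) else 1e-300
  mr_estimate_row(if (weighted) "weighted_mode" else "simple_mode",
                  nrow(data), beta, se, pval, level)
}

#' Run a battery of MR estimators
#'
#' Convenience wrapper running the requested methods on one harmonized
#' instrument set and row-binding the estimates. Methods whose minimum
#' instrument count exceeds J are skipped silently, so the same call works
#' across pairs with few instruments.
#'
#' @param data Harmonized instrument tibble.
#' @param methods Character vector from `"ivw"`, `"ivw_fixed"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`, `"wald"`.
#' @param n_boot,seed,phi,level Passed to the individual estimators; each
#'   bootstrap method receives its own sub-seed derived from `seed`.
#' @return An `mr_estimate` tibble, one row per method run.
#' @export
mr_all <- function(data,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   n_boot = 1000, seed = 1, phi = 1, level = 0.95) {
  J <- nrow(data)
  runners <- list(
    wald = list(min = 1L, fun = function() mr_wald_ratio(data, level)),
    ivw = list(min = 1L, fun = function() mr_ivw(data, "random_multiplicative", level)),
    ivw_fixed = list(min = 1L, fun = function() mr_ivw(data, "fixed", level)),
    egger = list(min = 3L, fun = function() mr_egger(data, level)),
    weighted_median = list(min = 3L, fun = function()
      mr_weighted_median(data, n_boot, derive_seed(seed, 11L), level)),
    simple_mode = list(min = 3L, fun = function()
      mr_mode(data, FALSE, phi, n_boot, derive_seed(seed, 12L), level)),
    weighted_mode = list(min = 3L, fun = function()
      mr_mode(data, TRUE, phi, n_boot, derive_seed(seed, 13L), level))
  )
  unknown <- setdiff(methods, names(runners))
  if (length(unknown) > 0L) {
    stop_config(paste0("unknown method(s): ", paste(unknown, collapse = ", ")))
  }
  rows <- purrr::map(methods, function(m) {
    if (J < runners[[m]]$min) return(NULL)
    runners[[m]]$fun()
  })
  dplyr::bind_rows(rows)
}
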