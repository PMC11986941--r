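# Estimator correctness against closed forms and independent oracles.

test_that("Wald ratio follows the first-order formulas", {
  one <- tibble::tibble(beta_exposure = 0.1, se_exposure = 0.005,
                        beta_outcome = 0.05, se_outcome = 0.01)
  est <- mr_wald_ratio(one)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)

  neg <- dplyr::mutate(one, beta_exposure = -0.1, beta_outcome = -0.05)
  expect_equal(mr_wald_ratio(neg)$beta, 0.5)

  zero <- dplyr::mutate(one, beta_exposure = 0)
  expect_error(mr_wald_ratio(zero), class = "targetmr_input_error")
})

test_that("IVW collapses correctly in the collinear and single-SNP cases", {
  dat <- tibble::tibble(beta_exposure = c(0.1, 0.2), se_exposure = 0.01,
                        beta_outcome = c(0.05, 0.10), se_outcome = 0.01)
  fixed <- mr_ivw(dat, "fixed")
  random <- mr_ivw(dat)
  expect_equal(fixed$beta, 0.5)
  expect_equal(cochran_q(dat)$q, 0)
  expect_equal(random$se, fixed$se)  # Q = 0 -> no inflation

  one <- dat[1, ]
  expect_equal(mr_ivw(one)$beta, mr_wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, mr_wald_ratio(one)$se)
  expect_error(mr_ivw(dat[0, ]), class = "targetmr_insufficient_instruments")
})

test_that("IVW equals the weighted-least-squares oracle and the weighted
           mean of Wald ratios", {
  dat <- tibble::tibble(
    beta_exposure = c(0.1, 0.2, 0.15),
    se_exposure = c(0.01, 0.01, 0.01),
    beta_outcome = c(0.06, 0.09, 0.075),
    se_outcome = c(0.01, 0.02, 0.015))
  want <- wls_origin_oracle(dat$beta_exposure, dat$beta_outcome,
                            dat$se_outcome)
  expect_equal(mr_ivw(dat, "fixed")$beta, want$beta)
  expect_equal(mr_ivw(dat, "fixed")$se, want$se_fixed)
  expect_equal(mr_ivw(dat)$se, want$se_random)

  # algebraic identity: IVW = inverse-variance mean of ratios with g^2/sy^2
  ratios <- dat$beta_outcome / dat$beta_exposure
  w <- dat$beta_exposure^2 / dat$se_outcome^2
  expect_equal(mr_ivw(dat, "fixed")$beta, sum(w * ratios) / sum(w))
})

test_that("random-effects IVW never deflates below the fixed-effect SE", {
  for (s in 1:20) {
    dat <- random_instruments(withr::with_seed(s, sample(3:25, 1)), seed = s)
    expect_gte(mr_ivw(dat)$se, mr_ivw(dat, "fixed")$se)
  }
})

test_that("MR-Egger reproduces a noiseless line and the WLS oracle", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  dat <- tibble::tibble(beta_exposure = g, se_exposure = 0.01,
                        beta_outcome = 0.02 + 0.5 * g, se_outcome = 0.01)
  est <- mr_egger(dat)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.02, tolerance = 1e-12)

  dat5 <- random_instruments(5, seed = 21)
  want <- wls_egger_oracle(dat5$beta_exposure, dat5$beta_outcome,
                           dat5$se_outcome)
  got <- mr_egger(dat5)
  expect_equal(got$beta, want$slope)
  expect_equal(got$se, want$se_slope)
  expect_equal(got$egger_intercept, want$intercept)
  expect_equal(got$egger_intercept_se, want$se_intercept)

  expect_error(mr_egger(dat5[1:2, ]),
               class = "targetmr_insufficient_instruments")
})

test_that("MR-Egger recovers the causal slope under balanced pleiotropy", {
  sim <- simulate_dataset(sim_config(J = 50, beta_true = 0.3,
                                     pleiotropy_fraction = 1,
                                     pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                                     full_scale = TRUE, seed = 1))
  est <- mr_egger(sim_instruments(sim))
  expect_lt(abs(est$beta - 0.3), 2 * est$se)
})

test_that("weighted median interpolates cumulative weight midpoints", {
  dat <- tibble::tibble(beta_exposure = 1, se_exposure = 0.01,
                        beta_outcome = c(0.1, 0.2, 0.9), se_outcome = 1)
  est <- mr_weighted_median(dat, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)

  # all ratios equal: point estimate exact, bootstrap SE shrinks with noise
  same <- tibble::tibble(beta_exposure = c(0.1, 0.2, 0.3),
                         se_exposure = 1e-6,
                         beta_outcome = 0.7 * c(0.1, 0.2, 0.3),
                         se_outcome = 1e-6)
  est2 <- mr_weighted_median(same, n_boot = 100, seed = 2)
  expect_equal(est2$beta, 0.7)
  expect_lt(est2$se, 1e-4)

  # median property: estimate within the ratio range
  for (s in 1:10) {
    d <- random_instruments(7, seed = 100 + s)
    r <- d$beta_outcome / d$beta_exposure
    b <- mr_weighted_median(d, n_boot = 10, seed = s)$beta
    expect_gte(b, min(r))
    expect_lte(b, max(r))
  }
})

test_that("mode estimators find the dominant cluster, not the mean", {
  dat <- tibble::tibble(beta_exposure = 1, se_exposure = 0.01,
                        beta_outcome = c(0.5, 0.5, 0.5, 5.0), se_outcome = 0.1)
  est <- mr_mode(dat, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(est$beta - 0.5), 0.2)
  expect_gt(abs(est$beta - mean(c(0.5, 0.5, 0.5, 5.0))), 0.5)

  # independent oracle: argmax of the same-kernel density on a fine grid
  r <- dat$beta_outcome / dat$beta_exposure
  h <- 0.9 * min(sd(r), IQR(r) / 1.349) * length(r)^(-1/5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20001)
  dens <- vapply(grid, function(x) sum(dnorm((x - r) / h)), numeric(1))
  expect_lt(abs(est$beta - grid[which.max(dens)]), 0.01)

  # tight cluster limit
  tight <- tibble::tibble(beta_exposure = 1, se_exposure = 1e-4,
                          beta_outcome = 0.3 + c(-1e-3, 0, 1e-3),
                          se_outcome = 0.01)
  expect_lt(abs(mr_mode(tight, n_boot = 20, seed = 1)$beta - 0.3), 2e-3)

  # a single high-precision SNP pulls the weighted mode toward itself
  pull <- tibble::tibble(
    beta_exposure = 1, se_exposure = 0.001,
    beta_outcome = c(0.2, 0.21, 0.19, 0.8),
    se_outcome = c(0.5, 0.5, 0.5, 0.005))
  simple <- mr_mode(pull, weighted = FALSE, n_boot = 20, seed = 1)$beta
  weighted <- mr_mode(pull, weighted = TRUE, n_boot = 20, seed = 1)$beta
  expect_gt(weighted, simple)
  expect_gt(weighted, 0.5)

  # degenerate bandwidth: all ratios identical
  flat <- tibble::tibble(beta_exposure = c(1, 2, 4), se_exposure = 0.01,
                         beta_outcome = 0.25 * c(1, 2, 4), se_outcome = 0.01)
  expect_equal(mr_mode(flat, n_boot = 20, seed = 1)$beta, 0.25)
})

test_that("odds-ratio conversion matches independently computed endpoints", {
  flat <- to_odds_ratio(0, 0.1)
  expect_equal(flat$or, 1)
  expect_equal(flat$ci_low * flat$ci_high, 1)  # symmetric about 1 on log scale

  collapsed <- to_odds_ratio(log(2), 1e-12)
  expect_equal(collapsed$or, 2)
  expect_equal(collapsed$ci_low, 2, tolerance = 1e-9)

  # frozen from exp(0.631 -/+ qnorm(0.975) * 0.115) computed separately
  got <- to_odds_ratio(0.631, 0.115)
  expect_equal(got$or, 1.87948912896191, tolerance = 1e-12)
  expect_equal(got$ci_low, 1.50020856500304, tolerance = 1e-10)
  expect_equal(got$ci_high, 2.35465885763614, tolerance = 1e-10)
})

test_that("estimators are invariant to SNP ordering and bootstraps are
           seed-reproducible", {
  dat <- random_instruments(12, seed = 31)
  perm <- dat[withr::with_seed(1, sample(12)), ]
  expect_equal(mr_ivw(perm)$beta, mr_ivw(dat)$beta)
  expect_equal(mr_egger(perm)$beta, mr_egger(dat)$beta)
  expect_equal(mr_weighted_median(perm, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(dat, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)

  a <- mr_weighted_median(dat, n_boot = 200, seed = 99)
  b <- mr_weighted_median(dat, n_boot = 200, seed = 99)
  c <- mr_weighted_median(dat, n_boot = 200, seed = 100)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))

  m1 <- mr_mode(dat, weighted = TRUE, n_boot = 100, seed = 5)
  m2 <- mr_mode(dat, weighted = TRUE, n_boot = 100, seed = 5)
  expect_identical(m1$se, m2$se)
})

test_that("the battery wrapper respects instrument-count minima", {
  dat <- random_instruments(2, seed = 41)
  est <- mr_all(dat, n_boot = 10, seed = 1)
  expect_equal(est$method, "ivw_random")  # 3+-SNP methods skipped

  full <- mr_all(random_instruments(10, seed = 42), n_boot = 10, seed = 1)
  expect_setequal(full$method, c("ivw_random", "egger", "weighted_median",
                                 "simple_mode", "weighted_mode"))
  expect_error(mr_all(dat, methods = "nope"), class = "targetmr_config_error")
})
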