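# Cis-instrument selection: window, significance/MAF, clumping, F,
# confounder screen, and the assembled cascade.

mini_records <- function(pos, chrom = "1", pval = 1e-10, eaf = 0.3,
                         beta = 0.1, se = 0.01) {
  n <- length(pos)
  tibble::tibble(variant_id = sprintf("m%02d", seq_len(n)), chrom = chrom,
                 pos = pos, effect_allele = "A", other_allele = "G",
                 eaf = eaf, beta = beta, se = se, pval = pval, n = 1000)
}

test_that("gene-window filter uses inclusive 1-based bounds and chromosome", {
  region <- gene_region("X1", "1", 1000, 2000)
  dat <- mini_records(c(950, 2150, 1000, 2100))
  kept <- filter_gene_window(dat, region, flank_bp = 100)
  expect_equal(kept$pos, c(950, 1000, 2100))

  expect_equal(filter_gene_window(mini_records(1000), region, 0)$pos, 1000)
  expect_equal(nrow(filter_gene_window(mini_records(999), region, 0)), 0L)

  other <- mini_records(1500, chrom = "2")
  expect_equal(nrow(filter_gene_window(other, region, 100)), 0L)
})

test_that("significance and MAF thresholds are strict", {
  dat <- mini_records(1:3, pval = c(5e-8, 1e-9, 1e-9),
                      eaf = c(0.3, 0.995, 0.3))
  kept <- filter_significance(dat, p_max = 5e-8, maf_min = 0.01)
  expect_equal(kept$variant_id, "m03")  # m01: p not < 5e-8; m02: MAF 0.005
})

test_that("greedy clumping keeps the hand-traced set", {
  dat <- mini_records(1:3, pval = c(1e-20, 1e-15, 1e-10))
  ld <- diag(1, 3)
  dimnames(ld) <- list(dat$variant_id, dat$variant_id)
  ld["m01", "m02"] <- ld["m02", "m01"] <- 0.5
  ld["m01", "m03"] <- ld["m03", "m01"] <- 0.1
  ld["m02", "m03"] <- ld["m03", "m02"] <- 0.1
  kept <- greedy_clump(dat, ld, r2_max = 0.3)
  expect_equal(kept$variant_id, c("m01", "m03"))

  eye <- diag(1, 3)
  dimnames(eye) <- dimnames(ld)
  expect_equal(nrow(greedy_clump(dat, eye, 0.3)), 3L)
  expect_equal(nrow(greedy_clump(dat, ld, r2_max = 1.0)), 3L)  # strict >
})

test_that("clumping errors on missing variants unless told to assume
           independence", {
  dat <- mini_records(1:2, pval = c(1e-20, 1e-10))
  ld <- diag(1, 1)
  dimnames(ld) <- list("m01", "m01")
  expect_error(greedy_clump(dat, ld, 0.3), class = "targetmr_input_error")
  kept <- greedy_clump(dat, ld, 0.3, assume_independent = TRUE)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "ld_missing"), "m02")
})

test_that("clumping is invariant to input row order and matches the
           recursive oracle", {
  for (s in 1:50) {
    J <- withr::with_seed(s, sample(2:10, 1))
    dat <- withr::with_seed(s + 1000, {
      d <- mini_records(seq_len(J), pval = 10^-runif(J, 5, 20),
                        beta = rnorm(J, 0, 0.1))
      d
    })
    ld <- random_ld(dat$variant_id, seed = s + 2000)
    r2max <- withr::with_seed(s + 3000, runif(1, 0.1, 0.9))

    got <- greedy_clump(dat, ld, r2max)
    want <- clump_oracle(dat, ld, r2max)
    expect_equal(got$variant_id, want$variant_id)

    shuffled <- dat[withr::with_seed(s, sample(J)), ]
    expect_equal(greedy_clump(shuffled, ld, r2max)$variant_id,
                 got$variant_id)

    # retained pairs all at or below the threshold
    if (nrow(got) > 1) {
      sub <- ld[got$variant_id, got$variant_id]
      expect_true(all(sub[upper.tri(sub)] <= r2max))
    }
  }
})

test_that("F statistics follow both formulas and flag weak instruments", {
  dat <- mini_records(1:3, beta = c(0.1, 0, 0.0316), se = 0.01)
  f <- f_statistic(dat)
  expect_equal(f[1], 100)
  expect_equal(f[2], 0)
  expect_lt(f[3], 10)

  # variance-explained form on a strong instrument
  one <- mini_records(1, beta = 0.1, se = 0.01, eaf = 0.3)
  one$n <- 173082
  f_r2 <- f_statistic(one, method = "r2")
  r2 <- 2 * 0.3 * 0.7 * 0.1^2
  expect_equal(f_r2, r2 * (173082 - 2) / (1 - r2))
})

test_that("confounder screen removes only confounder/outcome hits below the
           threshold", {
  dat <- mini_records(1:3)
  assoc <- tibble::tibble(
    variant_id = c("m01", "m02", "m03"),
    trait_name = c("BMI", "BMI", "height"),
    pval = c(1e-8, 1e-4, 1e-20),
    category = c("confounder", "confounder", "other"))
  kept <- screen_confounders(dat, assoc, p_max = 1e-5)
  expect_equal(kept$variant_id, c("m02", "m03"))
  expect_equal(attr(kept, "removals")$trait_name, "BMI")
})

test_that("the full cascade returns exactly the constructed survivors with a
           reconciling audit", {
  fx <- make_selection_fixture()
  sel <- select_instruments(fx$data, fx$region, fx$ld, fx$assoc, fx$params)
  expect_setequal(sel$variant_id, fx$expected)

  audit <- attr(sel, "audit")
  expect_equal(audit$n_in[1], 50L)
  expect_equal(audit$n_out[nrow(audit)], length(fx$expected))
  # counts non-increasing and stage-reconciling
  expect_true(all(diff(audit$n_out) <= 0 | audit$n_in[-1] == audit$n_out[-nrow(audit)]))
  expect_equal(audit$n_in - audit$n_removed, audit$n_out)
  expect_equal(audit$n_in[-1], audit$n_out[-nrow(audit)])
})

test_that("permissive thresholds keep every in-window strong instrument, and
           a fully flagged set empties with an intact audit", {
  fx <- make_selection_fixture()
  loose <- selection_params(p_max = 1 - 1e-12, maf_min = 1e-4, r2_max = 1,
                            f_min = 10)
  sel <- select_instruments(fx$data, fx$region, fx$ld, NULL, loose)
  in_window <- filter_gene_window(fx$data, fx$region, loose$flank_bp)
  strong <- in_window[f_statistic(in_window) > 10, ]
  expect_setequal(sel$variant_id, strong$variant_id)

  all_flagged <- tibble::tibble(
    variant_id = fx$data$variant_id,
    trait_name = "BMI", pval = 1e-9, category = "confounder")
  expect_warning(
    sel2 <- select_instruments(fx$data, fx$region, fx$ld, all_flagged,
                               fx$params),
    "no instruments")
  expect_equal(nrow(sel2), 0L)
  audit2 <- attr(sel2, "audit")
  expect_equal(nrow(audit2), 5L)
  expect_equal(audit2$n_out[5], 0L)
})
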