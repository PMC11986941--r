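# Fixtures built in code: a 50-variant selection-cascade region with known
# survivors, a heterogeneity-planted pair, and a small multi-target study.

z_to_p <- function(z) 2 * pnorm(-abs(z))

# Deterministic 50-SNP region exercising every stage of the cascade.
# Expected survivors are known by construction:
#   s01-s05  fail the gene window (position or chromosome)
#   s06-s10  fail genome-wide significance
#   s11-s13  fail the MAF filter
#   s14-s33  ten LD pairs (r2 = 0.5); the higher-p partner of each is clumped
#   s34-s36  pass p but fail the F filter (f_min = 50 in the fixture params)
#   s37-s40  flagged as confounder-associated at p = 1e-8
#   s41-s50  clean survivors
# -> survivors: the ten pair leads s14,s16,...,s32 plus s41..s50 (20 SNPs).
make_selection_fixture <- function() {
  region <- gene_region("FIX1", "5", 74632154, 74657929)
  flank <- 100000
  in_pos <- function(i) region$start + 200 * i   # comfortably inside window
  n <- 50
  id <- sprintf("s%02d", 1:n)
  pos <- in_pos(1:n)
  chrom <- rep(region$chrom, n)
  eaf <- rep(0.3, n)
  z <- rep(20, n)

  pos[1:3] <- region$end + flank + c(1, 1000, 5e6)
  chrom[4:5] <- "6"
  z[6:10] <- 5                       # p ~ 5.7e-7, above 5e-8
  eaf[11:13] <- c(0.005, 0.995, 0.01)
  lead <- seq(14, 32, by = 2)
  partner <- lead + 1
  z[lead] <- 20 + 0.1 * seq_along(lead)
  z[partner] <- 15
  z[34:36] <- 6                      # p ~ 2e-9 passes, F = 36 < 50 fails
  z[37:40] <- 19 + 0.1 * (1:4)
  z[41:50] <- 18 + 0.1 * (1:10)

  se <- rep(0.01, n)
  data <- tibble::tibble(
    variant_id = id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = z * se, se = se, pval = z_to_p(z), n = 173082)

  ld <- diag(1, n)
  dimnames(ld) <- list(id, id)
  for (k in seq_along(lead)) {
    ld[lead[k], partner[k]] <- 0.5
    ld[partner[k], lead[k]] <- 0.5
  }

  assoc <- tibble::tibble(
    variant_id = c(id[37:40], "s41", "s42"),
    trait_name = c(rep("body mass index", 4), "smoking", "ldl cholesterol"),
    pval = c(rep(1e-8, 4), 1e-4, 1e-20),
    category = c(rep("confounder", 4), "confounder", "other"))

  expected <- c(id[lead], id[41:50])
  list(data = data, ld = ld, assoc = assoc, region = region,
       params = selection_params(f_min = 50), expected = expected)
}

# A target-outcome pair with planted heterogeneity carried by LD partners:
# blocks of two variants at r2 = 0.2 survive clumping together at r2 <= 0.3,
# but the pleiotropic (higher-p) partner is clumped away at r2 <= 0.1.
make_heterogeneous_pair <- function(n_blocks = 12, beta_true = 0.5) {
  J <- 2 * n_blocks
  id <- sprintf("h%02d", 1:J)
  region <- gene_region("HET1", "2", 1e6, 1e6 + 10 * J)
  lead <- seq(1, J, by = 2)
  partner <- lead + 1
  gamma <- numeric(J)
  gamma[lead] <- 0.10 + 0.002 * seq_along(lead)
  gamma[partner] <- 0.08 + 0.002 * seq_along(partner)
  se_x <- rep(0.004, J)
  se_y <- rep(0.05, J)
  alpha <- numeric(J)
  alpha[partner] <- 0.3 * rep(c(1, -1), length.out = n_blocks)
  Gamma <- beta_true * gamma + alpha

  exposure <- tibble::tibble(
    variant_id = id, chrom = region$chrom, pos = region$start + 5 * (1:J),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = gamma, se = se_x, pval = z_to_p(gamma / se_x), n = 173082)
  outcome <- tibble::tibble(
    variant_id = id, chrom = region$chrom, pos = region$start + 5 * (1:J),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = Gamma, se = se_y, pval = z_to_p(Gamma / se_y),
    n = 31265, n_cases = 411, n_controls = 30854)

  ld <- diag(1, J)
  dimnames(ld) <- list(id, id)
  for (k in seq_along(lead)) {
    ld[lead[k], partner[k]] <- 0.2
    ld[partner[k], lead[k]] <- 0.2
  }
  list(exposure = exposure, outcome = outcome, ld = ld, region = region)
}

# Small synthetic study: 3 targets x (3 outcomes + positive control).
# Exposure draws are shared across outcomes of a target (same seed), so each
# outcome differs only in its causal truth.
make_synthetic_study <- function(seed = 1, J = 40) {
  specs <- list(
    list(symbol = "GENEA", chrom = "11", truth = c(control = -0.8,
         nephro = 0.5, retino = 0.5, neuro = 0.7)),
    list(symbol = "GENEB", chrom = "12", truth = c(control = -0.8,
         nephro = 0.25, retino = 0, neuro = 0.3)),
    list(symbol = "GENEC", chrom = "13", truth = c(control = -0.9,
         nephro = 0, retino = -0.6, neuro = 0)))
  outcome_names <- c("control", "nephro", "retino", "neuro")
  targets <- list()
  outcomes <- setNames(vector("list", 4), outcome_names)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    region <- gene_region(sp$symbol, sp$chrom, 1e6, 2e6)
    t_seed <- seed + 97 * i
    sims <- lapply(outcome_names, function(on) {
      # the positive control mimics a CHD-sized case-control GWAS (an order
      # of magnitude more cases than the complication outcomes)
      n_cases <- if (on == "control") 6080 else 411
      n_controls <- if (on == "control") 12350 else 30854
      simulate_dataset(sim_config(
        J = J, beta_true = sp$truth[[on]], region = region,
        n_cases = n_cases, n_controls = n_controls,
        ld_blocks = list(c(6, 0.5), c(4, 0.2)),
        palindromic_fraction = 0, seed = t_seed))
    })
    targets[[i]] <- list(region = region, exposure = sims[[1]]$exposure,
                         ld = sims[[1]]$ld)
    for (k in seq_along(outcome_names)) {
      outcomes[[outcome_names[k]]] <- dplyr::bind_rows(
        outcomes[[outcome_names[k]]], sims[[k]]$outcome)
    }
  }
  list(targets = targets, outcomes = outcomes)
}
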