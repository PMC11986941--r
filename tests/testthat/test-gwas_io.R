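# Readers, writers and their audit bookkeeping.

sumstat_text <- function(rows) {
  header <- "variant_id\tchrom\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn"
  paste(c(header, rows), collapse = "\n")
}

write_tmp <- function(text, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("well-formed summary statistics round-trip with a clean audit", {
  path <- write_tmp(sumstat_text(c(
    "rs1\t1\t100\tA\tG\t0.30\t0.10\t0.01\t1.52e-23\t1000",
    "rs2\t1\t200\tC\tT\t0.45\t-0.05\t0.012\t3.11e-5\t1000",
    "rs3\t1\t300\tG\tA\t0.10\t0.02\t0.02\t0.317\t1000")))
  dat <- read_summary_stats(path)
  expect_equal(nrow(dat), 3L)
  audit <- attr(dat, "audit")
  expect_equal(audit$rows_dropped, 0L)
  expect_equal(audit$rows_in, audit$rows_valid + audit$rows_dropped)

  # read -> write -> read is an identity on retained fields
  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(dat, out)
  dat2 <- read_summary_stats(out)
  expect_equal(as.data.frame(dat2), as.data.frame(dat))
})

test_that("invalid rows are dropped and counted, and the audit reconciles", {
  path <- write_tmp(sumstat_text(c(
    "rs1\t1\t100\tA\tG\t0.30\t0.10\t0.01\t1.52e-23\t1000",
    "rs2\t1\t200\tC\tT\t0.45\t-0.05\t0\t1e-4\t1000",     # se = 0
    "rs3\t1\t300\tG\tG\t0.10\t0.02\t0.02\t0.3\t1000",    # identical alleles
    "rs4\t1\t400\tA\tC\t1.2\t0.02\t0.02\t0.3\t1000",     # eaf out of range
    "rs5\t1\t500\tA\tN\t0.2\t0.02\t0.02\t0.3\t1000")))   # allele not ACGT
  dat <- read_summary_stats(path)
  audit <- attr(dat, "audit")
  expect_equal(nrow(dat), 1L)
  expect_equal(audit$rows_dropped, 4L)
  expect_equal(audit$rows_in, audit$rows_valid + audit$rows_dropped)
  expect_equal(audit$drop_reasons$nonpositive_se, 1L)
  expect_equal(audit$drop_reasons$identical_alleles, 1L)
})

test_that("lower-case alleles are upper-cased and commas are sniffed", {
  text <- paste(
    "variant_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n",
    "rs1,1,100,a,g,0.30,0.10,0.01,1.52e-23,1000", sep = "\n")
  dat <- read_summary_stats(write_tmp(text, ".csv"))
  expect_equal(dat$effect_allele, "A")
  expect_equal(dat$other_allele, "G")
})

test_that("a mapped-but-absent column is a configuration error, and rounded
           p-values only warn", {
  path <- write_tmp(sumstat_text("rs1\t1\t100\tA\tG\t0.3\t0.1\t0.01\t1.52e-23\t1000"))
  expect_error(
    read_summary_stats(path, column_map = c(variant_id = "rsid_col",
                                            beta = "beta", se = "se",
                                            pval = "pval", eaf = "eaf",
                                            chrom = "chrom", pos = "pos",
                                            effect_allele = "effect_allele",
                                            other_allele = "other_allele")),
    class = "targetmr_config_error")
  expect_error(read_summary_stats(path, column_map = "no_such_preset"),
               class = "targetmr_config_error")

  # z = 10 but reported p = 0.5: inconsistent by far more than a factor 10
  bad <- write_tmp(sumstat_text("rs1\t1\t100\tA\tG\t0.3\t0.1\t0.01\t0.5\t1000"))
  expect_warning(read_summary_stats(bad), "inconsistent")

  all_bad <- write_tmp(sumstat_text("rs1\t1\t100\tA\tG\t0.3\t0.1\t0\t0.5\t1000"))
  expect_error(read_summary_stats(all_bad), class = "targetmr_input_error")
})

ld_text <- function(body) paste(c("id\tv1\tv2", body), collapse = "\n")

test_that("LD matrix reader validates shape, range and symmetry", {
  good <- write_tmp(ld_text(c("v1\t1\t0", "v2\t0\t1")))
  m <- read_ld_matrix(good)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(rownames(m), c("v1", "v2"))

  high <- write_tmp(ld_text(c("v1\t1\t1.2", "v2\t1.2\t1")))
  expect_error(read_ld_matrix(high), class = "targetmr_format_error")

  asym <- write_tmp(ld_text(c("v1\t1\t0.5", "v2\t0.4\t1")))
  expect_error(read_ld_matrix(asym), class = "targetmr_format_error")

  nonsq <- write_tmp(paste(c("id\tv1\tv2\tv3", "v1\t1\t0\t0", "v2\t0\t1\t0"),
                           collapse = "\n"))
  expect_error(read_ld_matrix(nonsq), class = "targetmr_format_error")
})

test_that("trait-association reader enforces category labels and accepts
           empty tables", {
  head <- "variant_id\ttrait_name\tpval\tcategory"
  good <- write_tmp(paste(c(head, "rs1\tBMI\t1e-8\tconfounder",
                            "rs2\tCHD\t1e-6\toutcome"), collapse = "\n"))
  tab <- read_trait_associations(good)
  expect_equal(nrow(tab), 2L)

  typo <- write_tmp(paste(c(head, "rs1\tBMI\t1e-8\tcofounder"), collapse = "\n"))
  expect_error(read_trait_associations(typo), class = "targetmr_format_error")

  empty <- write_tmp(head)
  expect_equal(nrow(read_trait_associations(empty)), 0L)
})

test_that("report writer emits three files and a faithful JSON round-trip", {
  est <- mr_ivw(random_instruments(5, seed = 3))
  est <- dplyr::mutate(est, target = "HMGCR", outcome = "nephropathy",
                       r2_max = 0.3, rerun = FALSE, .before = 1L)
  report <- list(estimates = est,
                 sensitivity = dplyr::mutate(
                   cochran_q(random_instruments(5, seed = 3)),
                   target = "HMGCR", outcome = "nephropathy", .before = 1L),
                 parameters = list(r2_strict = 0.1), seeds = list(seed = 1L))
  dir <- withr::local_tempdir()
  paths <- write_mr_report(report, dir)
  expect_true(all(file.exists(paths)))

  tsv <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(tsv), 1L)
  expect_true(all(c("outcome", "target", "method", "n_snp", "pval", "beta",
                    "se", "or", "ci_low", "ci_high") %in% names(tsv)))

  back <- jsonlite::fromJSON(paths[3])
  expect_equal(back$estimates$beta, est$beta)       # full precision survives
  expect_equal(back$estimates$or, est$or)
  expect_equal(back$parameters$r2_strict, 0.1)

  # empty report: files with headers only
  dir2 <- withr::local_tempdir()
  p2 <- write_mr_report(list(), dir2)
  expect_equal(nrow(readr::read_tsv(p2[1], show_col_types = FALSE)), 0L)
})
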