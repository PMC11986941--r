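#' Define a gene region
#'
#' A cis window anchor for drug-target instrument selection. Coordinates are
#' 1-based and inclusive on both ends, the usual GWAS convention.
#'
#' @param symbol Gene symbol, e.g. `"HMGCR"`.
#' @param chrom Chromosome as a string (`"5"`, not `5` — kept as character so
#'   `"X"` works).
#' @param start,end 1-based inclusive coordinates with `start <= end`.
#'
#' @return A one-row tibble with columns `symbol`, `chrom`, `start`, `end`.
#' @examples
#' gene_region("NPC1L1", "7", 44552134, 44580914)
#' @export
gene_region <- function(symbol, chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop_input("gene_region: start must be <= end")
  }
  tibble::tibble(symbol = as.character(symbol), chrom = as.character(chrom),
                 start = start, end = end)
}

#' Built-in cis windows for the three LDL-C-lowering drug targets
#'
#' GRCh37 gene bodies for HMGCR, PCSK9 and NPC1L1. These are conveniences;
#' any [gene_region()] can be used instead, and users on GRCh38 data should
#' supply their own coordinates.
#'
#' @return A three-row tibble of gene regions.
#' @export
drug_target_regions <- function() {
  dplyr::bind_rows(
    gene_region("HMGCR", "5", 74632154, 74657929),
    gene_region("PCSK9", "1", 55505221, 55530525),
    gene_region("NPC1L1", "7", 44552134, 44580914)
  )
}

# Canonical field names for a summary-statistics table.
sumstat_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pval", "n")
binary_fields <- c("n_cases", "n_controls")

#' Column-name presets for common GWAS export layouts
#'
#' Maps canonical field names to the column headers used by some widely
#' distributed summary-statistics dumps. Pass one of these names (or your own
#' named character vector, canonical name -> file column) as `column_map` in
#' [read_summary_stats()].
#'
#' @return A named list of named character vectors.
#' @export
gwas_column_presets <- function() {
  list(
    standard = setNames(sumstat_fields, sumstat_fields),
    finngen = c(variant_id = "rsids", chrom = "#chrom", pos = "pos",
                effect_allele = "alt", other_allele = "ref", eaf = "af_alt",
                beta = "beta", se = "sebeta", pval = "pval"),
    glgc = c(variant_id = "rsID", chrom = "CHROM", pos = "POS_b37",
             effect_allele = "ALT", other_allele = "REF", eaf = "POOLED_ALT_AF",
             beta = "EFFECT_SIZE", se = "SE", pval = "pvalue", n = "N")
  )
}

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited text table (tab or comma, sniffed from the header) of
#' per-variant associations, renames columns to the canonical layout, and
#' drops rows that violate basic invariants (alleles outside A/C/G/T or equal,
#' `se <= 0`, `eaf` outside (0,1), `pval` outside (0,1]). Dropped rows are
#' counted per reason in the `audit` attribute; reported p-values that
#' disagree with `2 * pnorm(-|beta/se|)` by more than a factor of 10 trigger a
#' warning only, since published tables often carry rounded p-values.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Either the name of a preset in [gwas_column_presets()] or
#'   a named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, and for binary traits `n_cases`,
#'   `n_controls`) to columns present in the file. Defaults to the canonical
#'   names themselves.
#' @param trait_type `"continuous"` (effects in outcome SD per allele) or
#'   `"binary"` (log-odds per allele; `n_cases`/`n_controls` validated when
#'   mapped).
#'
#' @return A tibble of validated records with canonical column names and
#'   upper-cased alleles, plus an `audit` attribute: a list with `rows_in`,
#'   `rows_valid`, `rows_dropped`, and a per-reason count table.
#' @export
read_summary_stats <- function(path, column_map = "standard",
                               trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map))) {
    presets <- gwas_column_presets()
    if (!column_map %in% names(presets)) {
      stop_config(paste0("unknown column-map preset '", column_map, "'"))
    }
    column_map <- presets[[column_map]]
  }
  known <- c(sumstat_fields, binary_fields)
  bad <- setdiff(names(column_map), known)
  if (length(bad) > 0L) {
    stop_config(paste0("column_map has unknown canonical field(s): ",
                       paste(bad, collapse = ", ")))
  }

  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0L) {
    stop_config(paste0("mapped column(s) not found in ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }

  dat <- raw[unname(column_map)]
  names(dat) <- names(column_map)
  dat <- tibble::as_tibble(dat)
  for (col in intersect(c("pos", "eaf", "beta", "se", "pval", "n", binary_fields),
                        names(dat))) {
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  }
  for (col in intersect(c("effect_allele", "other_allele"), names(dat))) {
    dat[[col]] <- toupper(dat[[col]])
  }
  if (!"n" %in% names(dat) && all(binary_fields %in% names(dat))) {
    dat$n <- dat$n_cases + dat$n_controls
  }

  validate_sumstats(dat, trait_type = trait_type)
}

# Shared validator: drops invalid rows, attaches an audit attribute.
validate_sumstats <- function(dat, trait_type = "continuous") {
  rows_in <- nrow(dat)
  reasons <- character(0)
  drop <- rep(FALSE, rows_in)
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    fresh <- cond & !drop
    if (any(fresh)) reasons <<- c(reasons, rep(reason, sum(fresh)))
    drop <<- drop | cond
  }
  nucleotides <- c("A", "C", "G", "T")
  flag(!dat$effect_allele %in% nucleotides | !dat$other_allele %in% nucleotides,
       "allele_not_ACGT")
  flag(dat$effect_allele == dat$other_allele, "identical_alleles")
  flag(!is.finite(dat$se) | dat$se <= 0, "nonpositive_se")
  flag(!is.finite(dat$eaf) | dat$eaf <= 0 | dat$eaf >= 1, "eaf_out_of_range")
  flag(!is.finite(dat$pval) | dat$pval <= 0 | dat$pval > 1, "pval_out_of_range")
  flag(!is.finite(dat$beta), "missing_beta")
  if ("n" %in% names(dat)) flag(!is.finite(dat$n) | dat$n <= 0, "nonpositive_n")
  if (trait_type == "binary" && all(binary_fields %in% names(dat))) {
    flag(!is.finite(dat$n_cases) | dat$n_cases <= 0 |
           !is.finite(dat$n_controls) | dat$n_controls <= 0,
         "nonpositive_case_control_n")
  }

  valid <- dat[!drop, , drop = FALSE]
  if (nrow(valid) == 0L) stop_input("no valid summary-statistic rows after validation")

  # Rounded p-values are common; warn, never drop.
  p_implied <- 2 * pnorm(-abs(valid$beta / valid$se))
  inconsistent <- p_implied > 0 & valid$pval > 0 &
    (valid$pval / p_implied > 10 | p_implied / valid$pval > 10)
  if (any(inconsistent, na.rm = TRUE)) {
    warn(paste0(sum(inconsistent, na.rm = TRUE),
                " row(s) have p-values inconsistent with |beta/se| by >10x ",
                "(kept; likely rounding in the source table)"))
  }

  audit <- list(
    rows_in = rows_in,
    rows_valid = nrow(valid),
    rows_dropped = rows_in - nrow(valid),
    drop_reasons = as.list(table(reasons)),
    p_inconsistent = sum(inconsistent, na.rm = TRUE)
  )
  attr(valid, "audit") <- audit
  valid
}

#' Write summary statistics to a TSV file
#'
#' Inverse of [read_summary_stats()] for the canonical layout; numeric
#' columns are written at full double precision so read-write-read is an
#' identity on retained fields.
#'
#' @param data A tibble of canonical summary-statistic records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a square LD (r-squared) matrix
#'
#' Expects a delimited table with variant ids as the header row and in the
#' first column. Values must lie in \[0, 1\], the diagonal must be 1 and the
#' matrix symmetric to within 1e-6.
#'
#' @param path Path to the matrix file (tab or comma delimited).
#' @return A numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop_format("LD matrix is not square")
  if (!identical(ids, colnames(m))) {
    stop_format("LD matrix row ids do not match column ids")
  }
  dimnames(m) <- list(ids, ids)
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(m, tol = 1e-6) {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1 + tol)) {
    stop_format("LD matrix values must be finite and in [0, 1]")
  }
  if (any(abs(diag(m) - 1) > tol)) stop_format("LD matrix diagonal must be 1")
  if (any(abs(m - t(m)) > tol)) stop_format("LD matrix is not symmetric")
  m[m > 1] <- 1
  m
}

#' Read a trait-association table
#'
#' A local stand-in for database lookups of secondary trait associations
#' (e.g. a PhenoScanner export): one row per (variant, trait) pair with a
#' p-value and a category classifying the trait as a potential confounder, an
#' outcome, or other.
#'
#' @param path Path to a delimited file with columns `variant_id`,
#'   `trait_name`, `pval`, `category` (values `confounder`, `outcome`,
#'   `other`).
#' @return A validated tibble (possibly zero rows).
#' @export
read_trait_associations <- function(path) {
  delim <- sniff_delim(path)
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             variant_id = "c", trait_name = "c",
                             pval = "d", category = "c"))
  needed <- c("variant_id", "trait_name", "pval", "category")
  missing <- setdiff(needed, names(dat))
  if (length(missing) > 0L) {
    stop_format(paste0("trait-association table lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(dat$category), c("confounder", "outcome", "other"))
  if (length(bad_cat) > 0L) {
    stop_format(paste0("unknown trait category label(s): ",
                       paste(bad_cat, collapse = ", ")))
  }
  if (nrow(dat) > 0L && any(!is.finite(dat$pval) | dat$pval <= 0 | dat$pval > 1)) {
    stop_format("trait-association p-values must lie in (0, 1]")
  }
  tibble::as_tibble(dat[needed])
}

#' Write a Mendelian randomization report to disk
#'
#' Writes three files into `out_dir`: `estimates.tsv` (one row per
#' target-outcome-method, numerics rounded to 4 significant digits for
#' display), `sensitivity.tsv` (Q / Egger-intercept / MR-PRESSO summaries),
#' and `report.json` holding the full report — estimates and sensitivity at
#' full double precision plus the seeds and parameters used — for
#' machine-readable round-trips.
#'
#' @param report An `mr_pair` or `mr_study` object, or any list with
#'   `estimates` and `sensitivity` tibbles.
#' @param out_dir Output directory, created if absent.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_mr_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(paste0("cannot write to directory ", out_dir), class = "targetmr_io_error")
  }
  est <- report$estimates %||% empty_estimates()
  sens <- report$sensitivity %||% empty_sensitivity()

  est_disp <- dplyr::mutate(est, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4)))
  sens_disp <- dplyr::mutate(sens, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4)))
  paths <- file.path(out_dir, c("estimates.tsv", "sensitivity.tsv", "report.json"))
  readr::write_tsv(est_disp, paths[1], progress = FALSE)
  readr::write_tsv(sens_disp, paths[2], progress = FALSE)

  payload <- list(
    estimates = est,
    sensitivity = sens,
    parameters = report$parameters %||% list(),
    seeds = report$seeds %||% list()
  )
  jsonlite::write_json(payload, paths[3], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(paths)
}

empty_estimates <- function() {
  tibble::tibble(target = character(), outcome = character(),
                 method = character(), n_snp = integer(), beta = double(),
                 se = double(), pval = double(), or = double(),
                 ci_low = double(), ci_high = double(), r2_max = double(),
                 rerun = logical())
}

empty_sensitivity <- function() {
  tibble::tibble(target = character(), outcome = character(),
                 r2_max = double(), rerun = logical(), n_snp = integer(),
                 q = double(), q_df = integer(), q_pval = double(),
                 egger_intercept = double(), egger_intercept_se = double(),
                 egger_intercept_pval = double(), presso_global_pval = double(),
                 presso_n_outliers = integer(), presso_distortion_pval = double())
}
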