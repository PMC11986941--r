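#' Instrument-selection parameters
#'
#' Thresholds for the cis-instrument cascade. Defaults follow the standard
#' drug-target MR recipe: a +/-100 kb window around the gene body, genome-wide
#' significance p < 5e-8, minor allele frequency > 1%, greedy LD clumping at
#' r-squared 0.3, per-SNP F-statistic > 10, and removal of variants associated
#' with confounder traits or the outcome at p < 1e-5. All comparisons are
#' strict, matching the usual "<" / ">" phrasing of these cutoffs.
#'
#' @param flank_bp Window flank in base pairs (default 100000).
#' @param p_max Exposure significance threshold (keep `pval < p_max`).
#' @param maf_min Minimum minor allele frequency (keep `min(eaf, 1-eaf) > maf_min`).
#' @param r2_max LD clumping threshold (discard `r2 > r2_max` with a kept SNP).
#' @param f_min Weak-instrument cutoff (keep `F > f_min`).
#' @param confounder_p_max Confounder-screen threshold (drop trait
#'   associations with `pval < confounder_p_max`).
#'
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(flank_bp = 100000, p_max = 5e-8, maf_min = 0.01,
                             r2_max = 0.3, f_min = 10, confounder_p_max = 1e-5) {
  stopifnot(flank_bp >= 0, p_max > 0, p_max < 1, maf_min > 0,
            r2_max > 0, r2_max <= 1, f_min > 0, confounder_p_max > 0)
  structure(list(flank_bp = flank_bp, p_max = p_max, maf_min = maf_min,
                 r2_max = r2_max, f_min = f_min,
                 confounder_p_max = confounder_p_max),
            class = "selection_params")
}

#' Keep variants inside a cis gene window
#'
#' @param data Summary-statistics tibble with `chrom` and `pos`.
#' @param region A [gene_region()].
#' @param flank_bp Flank added on both sides of the gene body; the window
#'   `[start - flank_bp, end + flank_bp]` is inclusive.
#' @return The retained rows, input order preserved.
#' @export
filter_gene_window <- function(data, region, flank_bp = 100000) {
  dplyr::filter(data,
                .data$chrom == region$chrom,
                .data$pos >= region$start - flank_bp,
                .data$pos <= region$end + flank_bp)
}

#' Apply significance and minor-allele-frequency filters
#'
#' @param data Summary-statistics tibble.
#' @param p_max Keep rows with `pval < p_max` (strict).
#' @param maf_min Keep rows with `min(eaf, 1 - eaf) > maf_min` (strict).
#' @return The retained rows.
#' @export
filter_significance <- function(data, p_max = 5e-8, maf_min = 0.01) {
  dplyr::filter(data,
                .data$pval < p_max,
                pmin(.data$eaf, 1 - .data$eaf) > maf_min)
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending exposure p-value (ties broken by larger
#' `|beta|`, then lexicographic `variant_id`), keeping each index variant and
#' discarding all not-yet-kept variants with `r2 > r2_max` against it. The
#' result is p-ordered; every discarded variant has `r2 > r2_max` with some
#' retained variant of smaller-or-equal p, and all retained pairs have
#' `r2 <= r2_max`.
#'
#' @param data Summary-statistics tibble.
#' @param ld Square r-squared matrix with variant ids as dimnames (see
#'   [read_ld_matrix()]).
#' @param r2_max Discard threshold (strict `>`); `r2_max = 1` retains all.
#' @param assume_independent If `TRUE`, variants absent from `ld` are treated
#'   as unlinked (r2 = 0) and counted in the `ld_missing` attribute; if
#'   `FALSE` (default) a missing variant is an error.
#' @return The retained rows ordered by ascending p-value.
#' @export
greedy_clump <- function(data, ld, r2_max = 0.3, assume_independent = FALSE) {
  if (nrow(data) == 0L) return(data)
  missing <- setdiff(data$variant_id, rownames(ld))
  if (length(missing) > 0L && !assume_independent) {
    stop_input(paste0("variant(s) absent from LD matrix: ",
                      paste(head(missing, 5L), collapse = ", "),
                      if (length(missing) > 5L) ", ..." else ""))
  }

  ord <- order(data$pval, -abs(data$beta), data$variant_id)
  dat <- data[ord, , drop = FALSE]
  ids <- dat$variant_id
  keep <- logical(nrow(dat))
  alive <- rep(TRUE, nrow(dat))
  for (i in seq_len(nrow(dat))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    if (ids[i] %in% rownames(ld)) {
      cand <- which(alive & ids %in% colnames(ld))
      if (length(cand) > 0L) {
        r2 <- ld[ids[i], ids[cand]]
        alive[cand[r2 > r2_max]] <- FALSE
      }
    }
  }
  out <- dat[keep, , drop = FALSE]
  attr(out, "ld_missing") <- missing
  out
}

#' Per-SNP instrument-strength F-statistic
#'
#' The default form is the squared z-score, `F = (beta/se)^2`. An alternative
#' based on the variance explained, `F = R2 (n - 2) / (1 - R2)` with
#' `R2 = 2 maf (1 - maf) beta^2` (exposure in SD units), is available for
#' tables whose standard errors are not trusted; it requires `eaf` and `n`.
#'
#' @param data Summary-statistics tibble.
#' @param method `"z2"` (default) or `"r2"`.
#' @return Numeric vector of F-statistics, one per row.
#' @export
f_statistic <- function(data, method = c("z2", "r2")) {
  method <- match.arg(method)
  if (method == "z2") {
    (data$beta / data$se)^2
  } else {
    maf <- pmin(data$eaf, 1 - data$eaf)
    r2 <- 2 * maf * (1 - maf) * data$beta^2
    r2 * (data$n - 2) / (1 - r2)
  }
}

#' Screen instruments against secondary trait associations
#'
#' Removes variants reported as associated with a confounder trait or with an
#' outcome at `pval < p_max` in a local trait-association table (category
#' `other` never removes). Removals are recorded, with the trait names, in
#' the `removals` attribute.
#'
#' @param data Summary-statistics tibble.
#' @param assoc Trait-association tibble (see [read_trait_associations()]).
#' @param p_max Removal threshold (strict `<`).
#' @return The retained rows; attribute `removals` is a tibble of
#'   (variant_id, trait_name, pval) pairs that caused removal.
#' @export
screen_confounders <- function(data, assoc, p_max = 1e-5) {
  hits <- dplyr::filter(assoc,
                        .data$category %in% c("confounder", "outcome"),
                        .data$pval < p_max,
                        .data$variant_id %in% data$variant_id)
  out <- dplyr::filter(data, !.data$variant_id %in% hits$variant_id)
  attr(out, "removals") <- hits[c("variant_id", "trait_name", "pval")]
  out
}

#' Select cis instruments for a drug target
#'
#' Runs the full cascade — gene window, significance and MAF filters, greedy
#' LD clumping, F-statistic filter, confounder screen — in that order, and
#' returns the survivors together with a per-stage audit.
#'
#' @param data Exposure summary-statistics tibble.
#' @param region A [gene_region()].
#' @param ld LD r-squared matrix.
#' @param assoc Trait-association tibble; `NULL` skips the screen.
#' @param params A [selection_params()] object.
#' @param assume_independent Passed to [greedy_clump()].
#' @return The surviving instruments (tibble, p-ordered after clumping), with
#'   attribute `audit`: a tibble of per-stage counts satisfying
#'   `n_out = n_in - n_removed` at every stage, plus attribute `removals`
#'   from the confounder screen. Zero survivors is a warning, not an error.
#' @export
select_instruments <- function(data, region, ld, assoc = NULL,
                               params = selection_params(),
                               assume_independent = FALSE) {
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, n_removed = n_in - n_out)
  }

  n0 <- nrow(data)
  s1 <- filter_gene_window(data, region, params$flank_bp)
  note("gene_window", n0, nrow(s1))
  s2 <- filter_significance(s1, params$p_max, params$maf_min)
  note("significance_maf", nrow(s1), nrow(s2))
  s3 <- greedy_clump(s2, ld, params$r2_max, assume_independent)
  note("ld_clump", nrow(s2), nrow(s3))
  s4 <- s3[f_statistic(s3) > params$f_min, , drop = FALSE]
  note("f_statistic", nrow(s3), nrow(s4))
  if (!is.null(assoc)) {
    s5 <- screen_confounders(s4, assoc, params$confounder_p_max)
    removals <- attr(s5, "removals")
  } else {
    s5 <- s4
    removals <- NULL
  }
  note("confounder_screen", nrow(s4), nrow(s5))

  if (nrow(s5) == 0L) {
    warn(paste0("no instruments survive selection for ", region$symbol))
  }
  audit <- dplyr::bind_rows(stages)
  attr(s5, "audit") <- audit
  attr(s5, "removals") <- removals
  s5
}
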