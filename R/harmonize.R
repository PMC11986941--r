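#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele so that every
#' instrument carries (beta_exposure, se_exposure) and (beta_outcome,
#' se_outcome) on the same allele. Variants are matched by `variant_id`.
#' For each matched pair:
#'
#' * identical allele pair, same orientation — kept as-is (`kept`);
#' * swapped alleles — outcome beta negated and its frequency reflected
#'   (`flipped`);
#' * alleles matching after strand complement (e.g. A/G vs T/C) — outcome
#'   complemented, then the two rules above applied (`strand_complemented`);
#' * palindromic pair (A/T or C/G) — dropped when either source's effect
#'   allele frequency lies within `palindrome_window` of 0.5
#'   (`dropped_palindromic`), otherwise aligned by frequency concordance:
#'   if both frequencies sit on the same side of 0.5 the orientations agree,
#'   otherwise the outcome is flipped;
#' * anything else — `dropped_unmatched`.
#'
#' @param exposure,outcome Canonical summary-statistics tibbles (see
#'   [read_summary_stats()]). Duplicate `variant_id`s within either source
#'   are an error.
#' @param palindrome_window Half-width of the ambiguous frequency band around
#'   0.5 for palindromic variants. The default 0.08 (drop when eaf is in
#'   \[0.42, 0.58\]) is the common two-sample MR convention.
#'
#' @return A tibble of usable instruments with columns `variant_id`,
#'   `effect_allele`, `other_allele` (exposure coding), `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action`. The `audit` attribute records the action taken
#'   for every matched candidate (including dropped ones) and the count of
#'   exposure variants with no outcome match.
#' @export
harmonize <- function(exposure, outcome, palindrome_window = 0.08) {
  if (anyDuplicated(exposure$variant_id) > 0L) {
    stop_input("duplicate variant_id in exposure summary statistics")
  }
  if (anyDuplicated(outcome$variant_id) > 0L) {
    stop_input("duplicate variant_id in outcome summary statistics")
  }

  out_idx <- match(exposure$variant_id, outcome$variant_id)
  matched <- which(!is.na(out_idx))
  rows <- purrr::map(matched, function(i) {
    harmonize_one(exposure[i, ], outcome[out_idx[i], ], palindrome_window)
  })
  cand <- dplyr::bind_rows(rows)
  if (nrow(cand) == 0L) {
    cand <- tibble::tibble(variant_id = character(), effect_allele = character(),
                           other_allele = character(), beta_exposure = double(),
                           se_exposure = double(), eaf_exposure = double(),
                           beta_outcome = double(), se_outcome = double(),
                           eaf_outcome = double(), action = character())
  }
  kept <- dplyr::filter(cand, !startsWith(.data$action, "dropped"))
  attr(kept, "audit") <- list(
    candidates = cand[c("variant_id", "action")],
    n_exposure = nrow(exposure),
    n_matched = length(matched),
    n_unmatched_id = nrow(exposure) - length(matched),
    n_kept = nrow(kept)
  )
  kept
}

# One exposure/outcome record pair -> one harmonized candidate row.
harmonize_one <- function(ex, out, palindrome_window) {
  res <- tibble::tibble(
    variant_id = ex$variant_id,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    eaf_exposure = ex$eaf,
    beta_outcome = out$beta,
    se_outcome = out$se,
    eaf_outcome = out$eaf,
    action = "kept"
  )
  ea <- ex$effect_allele; oa <- ex$other_allele
  oea <- out$effect_allele; ooa <- out$other_allele

  if (is_palindromic(ea, oa)) {
    # Alleles alone cannot orient a palindromic pair; use frequencies.
    same_pair <- (oea == ea && ooa == oa) || (oea == oa && ooa == ea)
    if (!same_pair) {
      res$action <- "dropped_unmatched"
      return(res)
    }
    ambiguous <- abs(ex$eaf - 0.5) <= palindrome_window ||
      abs(out$eaf - 0.5) <= palindrome_window
    if (ambiguous) {
      res$action <- "dropped_palindromic"
      return(res)
    }
    concordant <- sign(ex$eaf - 0.5) == sign(out$eaf - 0.5)
    if (!concordant) {
      res$beta_outcome <- -out$beta
      res$eaf_outcome <- 1 - out$eaf
      res$action <- "flipped"
    }
    return(res)
  }

  if (oea == ea && ooa == oa) return(res)
  if (oea == oa && ooa == ea) {
    res$beta_outcome <- -out$beta
    res$eaf_outcome <- 1 - out$eaf
    res$action <- "flipped"
    return(res)
  }
  # Try the opposite strand.
  cea <- complement_allele(oea); coa <- complement_allele(ooa)
  if (!is.na(cea) && !is.na(coa)) {
    if (cea == ea && coa == oa) {
      res$action <- "strand_complemented"
      return(res)
    }
    if (cea == oa && coa == ea) {
      res$beta_outcome <- -out$beta
      res$eaf_outcome <- 1 - out$eaf
      res$action <- "strand_complemented"
      return(res)
    }
  }
  res$action <- "dropped_unmatched"
  res
}

#' Orient the exposure scale
#'
#' Two-sample MR of a drug target is usually reported on the drug-mimicking
#' scale — per standard-deviation *decrease* of the exposure — so that a
#' protective drug reads as OR < 1. `per_sd_decrease` negates every
#' `beta_exposure`, which flips the sign of all downstream causal slopes;
#' `per_sd_increase` is the identity. Applying the decrease orientation twice
#' restores the original scale.
#'
#' @param instruments A harmonized instrument tibble (see [harmonize()]).
#' @param direction `"per_sd_decrease"` (default) or `"per_sd_increase"`.
#' @return The instrument tibble, with attribute `direction` recording the
#'   orientation applied.
#' @export
orient_exposure <- function(instruments,
                            direction = c("per_sd_decrease", "per_sd_increase")) {
  direction <- match.arg(direction)
  if (direction == "per_sd_decrease") {
    instruments$beta_exposure <- -instruments$beta_exposure
  }
  attr(instruments, "direction") <- direction
  instruments
}
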