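# Internal helpers shared across modules.

# DNA complement for strand flips; anything else maps to NA.
complement_allele <- function(x) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[x])
}

# A/T and C/G pairs cannot be resolved from alleles alone.
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Sniff tab vs comma from the header line.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort("empty file: no header row", class = "targetmr_format_error")
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

stop_config <- function(msg) abort(msg, class = "targetmr_config_error")
stop_format <- function(msg) abort(msg, class = "targetmr_format_error")
stop_input  <- function(msg) abort(msg, class = "targetmr_input_error")

# Column checks for harmonized instrument tables.
instrument_cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")

check_instruments <- function(data, min_snp = 1L, caller = "estimator") {
  missing <- setdiff(instrument_cols, names(data))
  if (length(missing) > 0L) {
    stop_input(paste0(caller, ": instrument table lacks column(s) ",
                      paste(missing, collapse = ", ")))
  }
  if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0)) {
    stop_input(paste0(caller, ": all standard errors must be > 0"))
  }
  if (nrow(data) < min_snp) {
    abort(paste0(caller, " requires at least ", min_snp, " instrument(s), got ",
                 nrow(data)),
          class = "targetmr_insufficient_instruments")
  }
  invisible(data)
}

# Deterministic sub-seed derivation; keeps results reproducible from one
# user-facing seed while giving each stochastic component its own stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
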