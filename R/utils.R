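# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet `ACGTN` (case is
#' preserved for upper-case input; everything is upper-cased first).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AGGTA")
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Extract sequence[start0, end0) from a contig string (0-based half-open).
seq_range0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

# Single base at 0-based position, "" when out of range.
base_at0 <- function(seq, pos0) {
  substr(seq, pos0 + 1L, pos0 + 1L)
}

#' Round half away from zero at a fixed number of decimals
#'
#' The tables in this package print ratios and percentages rounded half-up
#' at two decimals (0.105 -> 0.11), unlike [base::round()]'s banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 32-bit-safe seed substream derived from a base seed and
# string labels: adding a strain never changes another strain's draws.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library functions do not perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uniform integer draws on [-j, j]; j = 0 gives zeros.
runif_int <- function(n, j) {
  if (j == 0) return(integer(n))
  as.integer(sample.int(2L * j + 1L, n, replace = TRUE)) - j - 1L
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
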