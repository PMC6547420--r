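# Boundary-variation statistics: the summed end-position difference
# between two deletion forms, its maximum over all form pairs of a locus,
# the published variation classes, and ratio tables over those classes.

VARIATION_CLASSES <- c("0", "1-10", "11-20", "21-30", "31-40", "41-50",
                       "51-60", "61-70", "71-80", "81-90", "91-100", ">100")

#' Boundary difference between two deletion forms
#'
#' The summed length difference at both ends, `|A1 - A2| + |B1 - B2|`.
#' A metric on (A, B) pairs.
#'
#' @param A1,B1,A2,B2 0-based half-open coordinates of the two forms
#'   (vectorized).
#' @param contig1,contig2 Optional contig labels; differing contigs error.
#' @return Non-negative integer vector.
#' @export
form_difference <- function(A1, B1, A2, B2, contig1 = NULL, contig2 = NULL) {
  if (!is.null(contig1) && !is.null(contig2) && any(contig1 != contig2)) {
    stop("forms on different contigs are not comparable", call. = FALSE)
  }
  abs(A1 - A2) + abs(B1 - B2)
}

#' Maximum boundary variation of a locus
#'
#' The maximum of [form_difference()] over all unordered pairs of forms
#' (0 for a single form). Intra-strain forms are included. Duplicate
#' forms and form order do not change the result.
#'
#' @param A,B Integer vectors: the forms' coordinates.
#' @return Non-negative integer.
#' @export
max_boundary_variation <- function(A, B) {
  n <- length(A)
  stopifnot(n >= 1, length(B) == n)
  if (n == 1) return(0L)
  dA <- abs(outer(A, A, "-"))
  dB <- abs(outer(B, B, "-"))
  as.integer(max(dA + dB))
}

# Per-end maxima: max |A_i - A_j| and max |B_i - B_j| separately.
end_variation <- function(A, B) {
  if (length(A) == 1) return(c(A = 0L, B = 0L))
  c(A = as.integer(max(A) - min(A)), B = as.integer(max(B) - min(B)))
}

#' Classify a maximum boundary variation into its published class
#'
#' Bins closed on both ends: "0"; "1-10"; ...; "91-100"; ">100".
#'
#' @param v Non-negative integer vector of variations.
#' @return Character vector of class labels (factor levels in
#'   `variation_classes()` order).
#' @export
classify_variation <- function(v) {
  if (any(v < 0)) stop("variation must be non-negative", call. = FALSE)
  idx <- ifelse(v == 0, 1L, ifelse(v > 100, 12L, 1L + ceiling(v / 10)))
  VARIATION_CLASSES[idx]
}

#' The ordered boundary-variation class labels
#' @return Character vector of the 12 class labels.
#' @export
variation_classes <- function() VARIATION_CLASSES

#' Per-locus variation records
#'
#' Computes the maximum boundary variation, form count and class label per
#' locus, optionally restricted to a strain subset.
#'
#' @param forms Output of [cluster_forms()].
#' @param strains Optional strain subset; default all strains present.
#' @param require_all If TRUE, only loci with at least one form in every
#'   queried strain are kept.
#' @return data.frame: locus_id, max_variation, n_forms, class_label.
#' @export
locus_variation <- function(forms, strains = NULL, require_all = FALSE) {
  stopifnot_cols(forms, c("locus_id", "strain", "A", "B"), "forms")
  if (!is.null(strains)) forms <- forms[forms$strain %in% strains, , drop = FALSE]
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  if (require_all && !is.null(strains)) {
    sp <- sp[vapply(sp, function(i) {
      all(strains %in% forms$strain[i])
    }, logical(1))]
  }
  if (length(sp) == 0) {
    return(data.frame(locus_id = character(0), max_variation = integer(0),
                      n_forms = integer(0), class_label = character(0)))
  }
  out <- data.frame(
    locus_id = names(sp),
    max_variation = vapply(sp, function(i) {
      max_boundary_variation(forms$A[i], forms$B[i])
    }, integer(1)),
    n_forms = lengths(sp),
    stringsAsFactors = FALSE
  )
  out$class_label <- classify_variation(out$max_variation)
  rownames(out) <- NULL
  out
}

#' Class histogram with percentages
#'
#' @param records Output of [locus_variation()].
#' @return data.frame: class_label, n, percent (half-up, 2 decimals).
#' @export
class_histogram <- function(records) {
  tab <- table(factor(records$class_label, levels = VARIATION_CLASSES))
  data.frame(
    class_label = VARIATION_CLASSES,
    n = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / max(1L, nrow(records)), 2),
    stringsAsFactors = FALSE
  )
}

#' Ratio table of flagged loci per variation class
#'
#' The per-class tabulation of all loci versus a flagged subset with the
#' flagged/total ratio, plus a Total row — the layout used to report
#' mutant-affected loci per variation class.
#'
#' @param records Output of [locus_variation()] for all loci.
#' @param flagged_ids Locus ids of the flagged subset (must be a subset of
#'   `records$locus_id`).
#' @return data.frame: class_label, total, flagged, ratio (half-up, 2
#'   decimals; NA for empty classes).
#' @export
ratio_table <- function(records, flagged_ids) {
  if (!all(flagged_ids %in% records$locus_id)) {
    stop("flagged_ids must be a subset of records$locus_id", call. = FALSE)
  }
  tot <- table(factor(records$class_label, levels = VARIATION_CLASSES))
  flg <- table(factor(records$class_label[records$locus_id %in% flagged_ids],
                      levels = VARIATION_CLASSES))
  ratio_cells(as.integer(tot), as.integer(flg))
}

#' Ratio-table arithmetic on per-class counts
#'
#' The reporting arithmetic behind [ratio_table()], exposed so published
#' count tables can be fed through the same code path: appends a Total row
#' and computes flagged/total rounded half-up at 2 decimals.
#'
#' @param total,flagged Integer vectors of per-class counts, in
#'   [variation_classes()] order.
#' @return data.frame: class_label, total, flagged, ratio.
#' @export
ratio_cells <- function(total, flagged) {
  stopifnot(length(total) == length(VARIATION_CLASSES),
            length(flagged) == length(total), all(flagged <= total))
  tot_all <- sum(total)
  flg_all <- sum(flagged)
  df <- data.frame(
    class_label = c(VARIATION_CLASSES, "Total"),
    total = c(total, tot_all),
    flagged = c(flagged, flg_all),
    stringsAsFactors = FALSE
  )
  df$ratio <- ifelse(df$total == 0, NA_real_,
                     round_half_up(df$flagged / df$total, 2))
  df
}
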