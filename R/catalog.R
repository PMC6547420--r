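# IES cataloguing: refined calls are normalized so the junction
# microhomology (terminal direct repeat) sits at the A-end, filtered by
# length and by Ns near the junctions, and clustered into loci by >= 1-bp
# interval overlap across strains.

#' Normalize a deletion junction to the A-end
#'
#' Terminal direct repeats make the exact breakpoint ambiguous: when the
#' base immediately left of A equals the last base of the deleted segment,
#' the interval can slide left without changing the rejoined somatic
#' product. The canonical representation shifts `[A, B)` to `[A-1, B-1)`
#' while `A > 0` and `seq[A-1] == seq[B-1]`, then records the maximal
#' microhomology length `m` with `seq[A..A+m) == seq[B..B+m)`.
#'
#' @param A,B 0-based half-open interval of the call.
#' @param seq Contig sequence (single string).
#' @return List with `A`, `B`, `mh_len`.
#' @examples
#' normalize_junction(3, 10, "ACGGATTTGGACG")  # shifts to [2, 9)
#' @export
normalize_junction <- function(A, B, seq) {
  stopifnot(A >= 0, B > A, B <= nchar(seq))
  raw <- charToRaw(seq)
  A <- as.integer(A); B <- as.integer(B)
  while (A > 0L && raw[A] == raw[B]) {  # raw is 1-based: raw[A] is seq[A-1]
    A <- A - 1L
    B <- B - 1L
  }
  n <- length(raw)
  m <- 0L
  while (A + m < B && B + m < n && raw[A + m + 1L] == raw[B + m + 1L]) {
    m <- m + 1L
  }
  list(A = A, B = B, mh_len = m)
}

#' Normalize a table of refined calls
#'
#' Applies [normalize_junction()] to every call against its contig
#' sequence and appends the microhomology length.
#'
#' @param calls data.frame with strain, contig, A, B (0-based half-open).
#' @param genome Named character vector of contig sequences.
#' @return `calls` with normalized A, B and an `mh_len` column.
#' @export
normalize_calls <- function(calls, genome) {
  stopifnot_cols(calls, c("contig", "A", "B"), "calls")
  if (nrow(calls) == 0) {
    calls$mh_len <- integer(0)
    return(calls)
  }
  bad <- setdiff(unique(calls$contig), names(genome))
  if (length(bad)) {
    stop("calls reference unknown contig(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mh <- integer(nrow(calls))
  for (ctg in unique(calls$contig)) {
    raw <- charToRaw(genome[[ctg]])
    n <- length(raw)
    idx <- which(calls$contig == ctg)
    for (i in idx) {
      a <- as.integer(calls$A[i]); b <- as.integer(calls$B[i])
      while (a > 0L && raw[a] == raw[b]) {
        a <- a - 1L
        b <- b - 1L
      }
      m <- 0L
      while (a + m < b && b + m < n && raw[a + m + 1L] == raw[b + m + 1L]) {
        m <- m + 1L
      }
      calls$A[i] <- a; calls$B[i] <- b; mh[i] <- m
    }
  }
  calls$mh_len <- mh
  calls
}

#' Filter normalized calls by length and junction Ns
#'
#' Removes calls shorter than `min_len` bp (strictly less) and calls with
#' an unknown nucleotide (N) within `n_guard` bases inside either end of
#' the deleted segment or within `n_guard` flanking bases on either side
#' (flank windows are truncated at contig edges). Input order is
#' preserved.
#'
#' @param calls Normalized calls (strain, contig, A, B, ...).
#' @param genome Named character vector of contig sequences.
#' @param min_len Minimum deletion length in bp (default 100).
#' @param n_guard Width of the N-check window at each junction (default 5).
#' @return The surviving subset of `calls`.
#' @export
filter_calls <- function(calls, genome, min_len = 100, n_guard = 5) {
  if (nrow(calls) == 0) return(calls)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- calls$A[i]; b <- calls$B[i]
    if (b - a < min_len) next
    seq <- genome[[calls$contig[i]]]
    len <- nchar(seq)
    zones <- paste0(
      seq_range0(seq, max(0L, a - n_guard), a),            # left flank
      seq_range0(seq, a, min(a + n_guard, b)),             # IES head
      seq_range0(seq, max(a, b - n_guard), b),             # IES tail
      seq_range0(seq, b, min(len, b + n_guard))            # right flank
    )
    keep[i] <- !grepl("N", zones, fixed = TRUE)
  }
  calls[keep, , drop = FALSE]
}

#' Cluster deletion forms into IES loci by interval overlap
#'
#' Deletions within or among strains that share at least 1 bp of overlap
#' are forms of the same IES. Clustering is single-linkage on the overlap
#' graph of half-open intervals (abutting intervals do not overlap), so a
#' chain of pairwise overlaps joins one locus even when its extremes are
#' disjoint. Duplicate identical (strain, contig, A, B) rows are collapsed
#' first. Locus ids are deterministic: `contig` plus the hull start.
#'
#' @param forms Filtered normalized calls (strain, contig, A, B, ...).
#' @return `forms` (deduplicated) with a `locus_id` column; the partition
#'   is invariant to input order.
#' @export
cluster_forms <- function(forms) {
  stopifnot_cols(forms, c("strain", "contig", "A", "B"), "forms")
  forms <- forms[!duplicated(forms[c("strain", "contig", "A", "B")]), ,
                 drop = FALSE]
  if (nrow(forms) == 0) {
    forms$locus_id <- character(0)
    return(forms)
  }
  forms$locus_id <- NA_character_
  for (ctg in unique(forms$contig)) {
    idx <- which(forms$contig == ctg)
    ir <- IRanges::IRanges(start = forms$A[idx] + 1L, end = forms$B[idx])
    # min.gapwidth = 0 merges only ranges sharing >= 1 base, not abutting
    hull <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, hull, select = "first")
    forms$locus_id[idx] <- sprintf("%s_%d", ctg, IRanges::start(hull)[hit] - 1L)
  }
  rownames(forms) <- NULL
  forms
}

#' Summarize clustered forms into a locus table
#'
#' @param forms Output of [cluster_forms()].
#' @return data.frame: locus_id, contig, span_start, span_end (hull,
#'   0-based half-open), n_forms, n_strains, strains (comma-joined sorted
#'   labels).
#' @export
locus_table <- function(forms) {
  stopifnot_cols(forms, c("locus_id", "strain", "contig", "A", "B"), "forms")
  if (nrow(forms) == 0) {
    return(data.frame(locus_id = character(0), contig = character(0),
                      span_start = integer(0), span_end = integer(0),
                      n_forms = integer(0), n_strains = integer(0),
                      strains = character(0)))
  }
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    i <- sp[[id]]
    data.frame(
      locus_id = id, contig = forms$contig[i[1]],
      span_start = min(forms$A[i]), span_end = max(forms$B[i]),
      n_forms = length(i), n_strains = length(unique(forms$strain[i])),
      strains = paste(sort(unique(forms$strain[i])), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$contig, out$span_start), ]
  rownames(out) <- NULL
  out
}

#' Count loci by the exact strain subset they occur in
#'
#' Venn-region counts: for every non-empty subset of `strains`, the number
#' of loci whose set of form-carrying strains equals exactly that subset.
#' Region counts sum to the number of loci.
#'
#' @param forms Output of [cluster_forms()].
#' @param strains Strain labels defining the universe.
#' @return data.frame: subset (comma-joined sorted labels), n_strains,
#'   n_loci — one row per non-empty subset, including empty regions.
#' @export
shared_locus_counts <- function(forms, strains) {
  stopifnot(length(strains) >= 1)
  forms <- forms[forms$strain %in% strains, , drop = FALSE]
  sig <- vapply(split(forms$strain, forms$locus_id), function(s) {
    paste(sort(unique(s)), collapse = ",")
  }, character(1))
  subsets <- unlist(lapply(seq_along(strains), function(k) {
    apply(utils::combn(sort(strains), k), 2, paste, collapse = ",")
  }))
  tab <- table(factor(sig, levels = subsets))
  data.frame(
    subset = subsets,
    n_strains = lengths(strsplit(subsets, ",", fixed = TRUE)),
    n_loci = as.integer(tab[subsets]),
    stringsAsFactors = FALSE
  )
}
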