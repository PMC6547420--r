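# Flanking regulatory sequence discovery: 100-bp flanks are extracted on
# each side of a locus, the downstream flank is reverse-complemented so an
# inverted repeat (IR) in genome coordinates appears as a literal k-mer
# match between the two processed flanks, all k-mer pairs with similar
# distances to the two ends are collected, and motif groups whose
# distance-to-boundary distributions are tightly concentrated (small IQR)
# are selected as candidate regulatory sequences.

#' Extract processed flank pair for one interval
#'
#' `left` is the W bp ending at the A-end read 5'->3'; `right_rc` is the
#' reverse complement of the W bp downstream of the B-end, so both strings
#' end at their junction and an inverted genomic repeat appears as an
#' identical substring of the two.
#'
#' @param A,B 0-based half-open interval.
#' @param seq Contig sequence.
#' @param W Flank width in bp (default 100).
#' @return List with `left`, `right_rc` (upper case, length W), or `NULL`
#'   when either flank would cross a contig end.
#' @export
extract_flanks <- function(A, B, seq, W = 100) {
  if (A - W < 0 || B + W > nchar(seq)) return(NULL)
  list(left = toupper(seq_range0(seq, A - W, A)),
       right_rc = revcomp(seq_range0(seq, B, B + W)))
}

#' Flank pairs for a catalogue of loci
#'
#' Uses the designated reference strain's form of each locus (the
#' lexicographically smallest (A, B) when that strain has several) as the
#' reference ends. Loci without a reference form or too close to a contig
#' end are excluded and listed in the `"excluded"` attribute.
#'
#' @param forms Output of [cluster_forms()].
#' @param genome Named character vector of contig sequences.
#' @param W Flank width in bp (default 100).
#' @param reference Reference strain label (default "CU427").
#' @return data.frame: locus_id, contig, A, B, left, right_rc; attribute
#'   `"excluded"` is a data.frame of locus_id + reason.
#' @export
locus_flanks <- function(forms, genome, W = 100, reference = "CU427") {
  stopifnot_cols(forms, c("locus_id", "strain", "contig", "A", "B"), "forms")
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  rows <- list()
  excluded <- list()
  for (id in names(sp)) {
    i <- sp[[id]]
    ri <- i[forms$strain[i] == reference]
    if (length(ri) == 0) {
      excluded[[id]] <- "no_reference_form"
      next
    }
    ri <- ri[order(forms$A[ri], forms$B[ri])][1]
    a <- forms$A[ri]; b <- forms$B[ri]
    fp <- extract_flanks(a, b, genome[[forms$contig[ri]]], W)
    if (is.null(fp)) {
      excluded[[id]] <- "flank_crosses_contig_end"
      next
    }
    rows[[id]] <- data.frame(
      locus_id = id, contig = forms$contig[ri], A = a, B = b,
      left = fp$left, right_rc = fp$right_rc, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), contig = character(0), A = integer(0),
               B = integer(0), left = character(0), right_rc = character(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) {
    data.frame(locus_id = names(excluded), reason = unlist(excluded),
               stringsAsFactors = FALSE)
  } else NULL
  out
}

# k-mers of a flank string with the distance from its junction-proximal
# base to the junction (flanks are junction-at-right: distance = W - i - k
# for 0-based start i).
flank_kmers <- function(s, k) {
  W <- nchar(s)
  starts <- seq_len(W - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  data.frame(kmer = km[keep], dist = W - (starts[keep] - 1L) - k,
             stringsAsFactors = FALSE)
}

#' Inverted-repeat k-mer pairs of one flank pair
#'
#' Enumerates every position pair where the k-mer in the left flank
#' literally equals a k-mer in the reverse-complemented right flank (an
#' inverted repeat in genome coordinates) and keeps pairs whose distances
#' to the respective IES ends differ by at most `max_dist_diff` bp.
#' Distances are measured from the IES end to the motif copy's
#' IES-proximal base (0 = motif abuts the junction). k-mers containing N
#' are skipped.
#'
#' @param left,right_rc Processed flanks from [extract_flanks()].
#' @param k k-mer length (default 5).
#' @param max_dist_diff Maximum |dA - dB| in bp (default 10).
#' @return data.frame: kmer, dA, dB, dist_diff.
#' @export
find_ir_pairs <- function(left, right_rc, k = 5, max_dist_diff = 10) {
  stopifnot(k <= nchar(left), nchar(left) == nchar(right_rc))
  l <- flank_kmers(left, k)
  r <- flank_kmers(right_rc, k)
  m <- merge(l, r, by = "kmer", suffixes = c("_l", "_r"))
  if (nrow(m) == 0) {
    return(data.frame(kmer = character(0), dA = integer(0), dB = integer(0),
                      dist_diff = integer(0)))
  }
  out <- data.frame(kmer = m$kmer, dA = m$dist_l, dB = m$dist_r,
                    dist_diff = abs(m$dist_l - m$dist_r),
                    stringsAsFactors = FALSE)
  out <- out[out$dist_diff <= max_dist_diff, , drop = FALSE]
  out <- out[order(out$kmer, out$dA, out$dB), ]
  rownames(out) <- NULL
  out
}

#' Direct-repeat k-mer pairs of one flank pair
#'
#' As [find_ir_pairs()] but the downstream flank is used in genome
#' orientation (no reverse complement), so matches are direct repeats.
#' `dB` is again measured from the B-end to the copy's IES-proximal base.
#'
#' @inheritParams find_ir_pairs
#' @return data.frame: kmer, dA, dB, dist_diff.
#' @export
find_dr_pairs <- function(left, right_rc, k = 5, max_dist_diff = 10) {
  stopifnot(k <= nchar(left), nchar(left) == nchar(right_rc))
  right <- revcomp(right_rc)  # back to genome orientation, junction at left
  l <- flank_kmers(left, k)
  W <- nchar(right)
  starts <- seq_len(W - k + 1L)
  km <- substring(right, starts, starts + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  r <- data.frame(kmer = km[keep], dist = starts[keep] - 1L,
                  stringsAsFactors = FALSE)
  m <- merge(l, r, by = "kmer", suffixes = c("_l", "_r"))
  if (nrow(m) == 0) {
    return(data.frame(kmer = character(0), dA = integer(0), dB = integer(0),
                      dist_diff = integer(0)))
  }
  out <- data.frame(kmer = m$kmer, dA = m$dist_l, dB = m$dist_r,
                    dist_diff = abs(m$dist_l - m$dist_r),
                    stringsAsFactors = FALSE)
  out <- out[out$dist_diff <= max_dist_diff, , drop = FALSE]
  out <- out[order(out$kmer, out$dA, out$dB), ]
  rownames(out) <- NULL
  out
}

#' Repeat-pair hits across a catalogue of flank pairs
#'
#' @param flanks Output of [locus_flanks()].
#' @param k k-mer length (default 5).
#' @param max_dist_diff Maximum |dA - dB| (default 10).
#' @param orientation "IR" (inverted, default) or "DR" (direct).
#' @return data.frame: locus_id, kmer, dA, dB, dist_diff.
#' @export
repeat_hits <- function(flanks, k = 5, max_dist_diff = 10,
                        orientation = c("IR", "DR")) {
  orientation <- match.arg(orientation)
  fun <- if (orientation == "IR") find_ir_pairs else find_dr_pairs
  rows <- lapply(seq_len(nrow(flanks)), function(i) {
    h <- fun(flanks$left[i], flanks$right_rc[i], k, max_dist_diff)
    if (nrow(h) == 0) return(NULL)
    cbind(locus_id = flanks$locus_id[i], h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(locus_id = character(0), kmer = character(0),
                      dA = integer(0), dB = integer(0), dist_diff = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional concentricity statistics per motif group
#'
#' For each k-mer (or supplied group label) the distance-to-boundary
#' distribution of its left-flank copies is summarized by the
#' interquartile range (linear-interpolation quantiles, type 7) and the
#' group is selected when `IQR <= iqr_max` and `count >= count_min` —
#' tightly placed repeats at a consistent distance from the deletion
#' boundary.
#'
#' @param hits data.frame of repeat hits (needs `kmer` and `dA`; `dB` is
#'   summarized too when present).
#' @param iqr_max IQR selection threshold in bp (default 10).
#' @param count_min Minimum number of contributing pairs (default 3).
#' @param qtype Quantile type passed to [stats::quantile()] (default 7).
#' @return data.frame sorted by count: kmer, count, median_dA, iqr,
#'   median_dB, iqr_dB, selected.
#' @export
concentricity <- function(hits, iqr_max = 10, count_min = 3, qtype = 7) {
  sp <- split(seq_len(nrow(hits)), hits$kmer)
  out <- do.call(rbind, lapply(names(sp), function(km) {
    i <- sp[[km]]
    q <- stats::quantile(hits$dA[i], c(0.25, 0.75), type = qtype, names = FALSE)
    has_b <- "dB" %in% names(hits)
    qb <- if (has_b) {
      stats::quantile(hits$dB[i], c(0.25, 0.75), type = qtype, names = FALSE)
    } else c(NA_real_, NA_real_)
    data.frame(
      kmer = km, count = length(i),
      median_dA = stats::median(hits$dA[i]), iqr = q[2] - q[1],
      median_dB = if (has_b) stats::median(hits$dB[i]) else NA_real_,
      iqr_dB = qb[2] - qb[1],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    out <- data.frame(kmer = character(0), count = integer(0),
                      median_dA = numeric(0), iqr = numeric(0),
                      median_dB = numeric(0), iqr_dB = numeric(0))
  }
  out$selected <- out$iqr <= iqr_max & out$count >= count_min
  out <- out[order(-out$count, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Pool hit groups sharing a core sequence
#'
#' Pools hits of all k-mers containing `core` as a substring (N in the
#' core matches any base) and recomputes the concentricity statistics on
#' the pooled distance vector.
#'
#' @param hits data.frame of repeat hits (kmer, dA, ...).
#' @param core Core sequence, possibly with N wildcards; shorter than or
#'   equal to the k-mer length.
#' @inheritParams concentricity
#' @return One-row data.frame as in [concentricity()] with the core as
#'   label.
#' @export
group_by_core <- function(hits, core, iqr_max = 10, count_min = 3, qtype = 7) {
  pat <- gsub("N", "[ACGT]", toupper(core), fixed = TRUE)
  keep <- grepl(pat, hits$kmer)
  pooled <- hits[keep, , drop = FALSE]
  if (nrow(pooled) == 0) {
    return(data.frame(kmer = core, count = 0L, median_dA = NA_real_,
                      iqr = NA_real_, median_dB = NA_real_, iqr_dB = NA_real_,
                      selected = FALSE, stringsAsFactors = FALSE))
  }
  pooled$kmer <- core
  concentricity(pooled, iqr_max, count_min, qtype)
}

#' Per-position nucleotide composition around deletion boundaries
#'
#' Pools, over loci, the base identities at each position from `-span`
#' (inside the deleted segment, adjacent to the junction) to `span - 1`
#' (flank). Both ends are pooled in a common junction-at-zero orientation:
#' A-end sequences are read outward along the plus strand and B-end
#' sequences are reverse-complemented, mirroring the processed-flank
#' convention. Ns are excluded from the per-position denominator.
#'
#' @param flanks_src data.frame with contig, A, B (e.g. [locus_flanks()]
#'   output or a truth table renamed accordingly).
#' @param genome Named character vector of contig sequences.
#' @param span Half-width in bp (default 500).
#' @param align "both" (default: pool A- and B-ends), "A-end" or "B-end".
#' @return data.frame: position (-span..span-1), A, C, G, T fractions
#'   (each row sums to 1), n (denominator).
#' @export
composition_profile <- function(flanks_src, genome, span = 500,
                                align = c("both", "A-end", "B-end")) {
  align <- match.arg(align)
  stopifnot_cols(flanks_src, c("contig", "A", "B"), "flanks_src")
  npos <- 2L * span
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = npos, ncol = 4, dimnames = list(NULL, bases))
  add_chars <- function(v) {
    # v: npos characters in axis order, index j = position j - span - 1
    for (b in bases) {
      hit <- which(v == b)
      if (length(hit)) counts[hit, b] <<- counts[hit, b] + 1L
    }
  }
  for (i in seq_len(nrow(flanks_src))) {
    a <- flanks_src$A[i]; b <- flanks_src$B[i]
    seq <- genome[[flanks_src$contig[i]]]
    if (align %in% c("both", "A-end") &&
        a - span >= 0 && a + span <= nchar(seq)) {
      # reversing the [a-span, a+span) slice puts IES bases on the negative
      # side and flank bases on the positive side, junction at 0, reading
      # the plus strand toward the junction
      slice <- strsplit(toupper(seq_range0(seq, a - span, a + span)), "",
                        fixed = TRUE)[[1]]
      add_chars(rev(slice))
    }
    if (align %in% c("both", "B-end") &&
        b - span >= 0 && b + span <= nchar(seq)) {
      # complementing (without reversing) the [b-span, b+span) slice gives
      # the same junction-at-zero orientation on the minus strand
      slice <- strsplit(chartr("ACGTN", "TGCAN",
                               toupper(seq_range0(seq, b - span, b + span))),
                        "", fixed = TRUE)[[1]]
      add_chars(slice)
    }
  }
  n <- rowSums(counts)
  frac <- counts / ifelse(n == 0, 1, n)
  data.frame(position = seq(-span, span - 1L),
             A = frac[, "A"], C = frac[, "C"], G = frac[, "G"],
             T = frac[, "T"], n = n)
}
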