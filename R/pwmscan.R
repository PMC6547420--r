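# Position weight matrix construction and flank scanning: PWMs built from
# aligned motif instances (pseudocount 1, log-odds against a uniform
# background) score candidate windows; scores are min-max normalized to a
# similarity in [0, 1] so "75% similarity" is an instance-set-independent
# threshold. G-rich and C-rich inverted-repeat arrangements are called
# from same-orientation hits in the two processed flanks, and each locus
# is assigned a single flanking regulatory sequence (FRS) type.

#' Build a position weight matrix from motif instances
#'
#' Per-position base counts with a pseudocount of 1 per base are converted
#' to log2-odds against a uniform 0.25 background (optionally an AT-biased
#' background). The minimal/maximal achievable window scores are stored
#' for min-max similarity normalization.
#'
#' @param instances Character vector (>= 2) of equal-length strings over
#'   ACGT.
#' @param label Optional label (e.g. "G-rich").
#' @param pseudocount Added to every per-position base count (default 1).
#' @param background Length-4 base probabilities (A, C, G, T), default
#'   uniform.
#' @return Object of class `"pwm"`: list(width, mat, s_min, s_max, label).
#' @export
build_pwm <- function(instances, label = "", pseudocount = 1,
                      background = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(instances) < 2) {
    stop("need at least 2 motif instances", call. = FALSE)
  }
  instances <- toupper(instances)
  w <- unique(nchar(instances))
  if (length(w) != 1) stop("instances must have equal length", call. = FALSE)
  if (any(grepl("[^ACGT]", instances))) {
    stop("instances must be strings over {A,C,G,T}", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  stopifnot(length(background) == 4, all(background > 0))
  chars <- do.call(rbind, strsplit(instances, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = bases))
    as.integer(tab)
  }, integer(4))
  n <- length(instances)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  mat <- log2(probs / background)
  rownames(mat) <- bases
  structure(list(width = w, mat = mat,
                 s_min = sum(apply(mat, 2, min)),
                 s_max = sum(apply(mat, 2, max)),
                 label = label),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, score range [%.3f, %.3f]\n",
              x$label, x$width, x$s_min, x$s_max))
  print(round(x$mat, 3))
  invisible(x)
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps complementary base rows, so the
#' returned matrix scores the reverse-complement motif.
#'
#' @param pwm A [build_pwm()] object.
#' @return A `"pwm"` object.
#' @export
revcomp_pwm <- function(pwm) {
  mat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(width = pwm$width, mat = mat,
                 s_min = pwm$s_min, s_max = pwm$s_max,
                 label = paste0(pwm$label, "-rc")),
            class = "pwm")
}

#' Min-max normalized PWM similarity of a window
#'
#' `(score - s_min) / (s_max - s_min)`: 1 at the consensus, 0 at the
#' per-position-worst window. Windows containing N return NA.
#'
#' @param pwm A [build_pwm()] object.
#' @param window String of length `pwm$width`.
#' @return Fraction in [0, 1], or NA for N-containing windows.
#' @export
pwm_similarity <- function(pwm, window) {
  window <- toupper(window)
  if (nchar(window) != pwm$width) {
    stop("window width must equal PWM width", call. = FALSE)
  }
  v <- strsplit(window, "", fixed = TRUE)[[1]]
  ridx <- match(v, rownames(pwm$mat))
  if (anyNA(ridx)) return(NA_real_)
  score <- sum(pwm$mat[cbind(ridx, seq_len(pwm$width))])
  (score - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

# All windows of a junction-at-right flank string with similarity >=
# threshold; dist = distance from the junction to the window's
# IES-proximal (last) base.
scan_flank_string <- function(s, pwm, threshold) {
  W <- nchar(s)
  k <- pwm$width
  if (k > W) {
    return(data.frame(dist = integer(0), similarity = numeric(0)))
  }
  starts <- seq_len(W - k + 1L)
  sim <- vapply(starts, function(i) {
    pwm_similarity(pwm, substr(s, i, i + k - 1L))
  }, numeric(1))
  keep <- !is.na(sim) & sim >= threshold
  data.frame(dist = W - (starts[keep] - 1L) - k, similarity = sim[keep])
}

#' Scan a flank pair for PWM inverted-repeat arrangements
#'
#' Both processed flanks (the downstream one already reverse-complemented)
#' are scanned with the PWM; hits at >= `threshold` similarity in the SAME
#' processed orientation on both sides whose distances to the respective
#' ends differ by at most `max_dist_diff` bp form an inverted-repeat call.
#' Scanning the same flanks with [revcomp_pwm()] yields the
#' opposite-strand (e.g. C-rich for a G-rich matrix) arrangement.
#'
#' @param left,right_rc Processed flanks (see [extract_flanks()]).
#' @param pwm A [build_pwm()] object.
#' @param threshold Minimum similarity in (0, 1]; comparison is inclusive.
#' @param max_dist_diff Maximum |dA - dB| in bp (default 10).
#' @return List with `hits` (side, dist, similarity) and `pairs`
#'   (dA, dB, dist_diff, sim_left, sim_right) sorted by (dist_diff,
#'   mean distance).
#' @export
scan_flanks <- function(left, right_rc, pwm, threshold, max_dist_diff = 10) {
  stopifnot(threshold > 0, threshold <= 1)
  hl <- scan_flank_string(left, pwm, threshold)
  hr <- scan_flank_string(right_rc, pwm, threshold)
  hits <- rbind(
    if (nrow(hl)) cbind(side = "left", hl) else NULL,
    if (nrow(hr)) cbind(side = "right", hr) else NULL
  )
  if (nrow(hl) == 0 || nrow(hr) == 0) {
    return(list(hits = hits,
                pairs = data.frame(dA = integer(0), dB = integer(0),
                                   dist_diff = integer(0),
                                   sim_left = numeric(0),
                                   sim_right = numeric(0))))
  }
  g <- expand.grid(il = seq_len(nrow(hl)), ir = seq_len(nrow(hr)))
  pairs <- data.frame(
    dA = hl$dist[g$il], dB = hr$dist[g$ir],
    dist_diff = abs(hl$dist[g$il] - hr$dist[g$ir]),
    sim_left = hl$similarity[g$il], sim_right = hr$similarity[g$ir]
  )
  pairs <- pairs[pairs$dist_diff <= max_dist_diff, , drop = FALSE]
  pairs <- pairs[order(pairs$dist_diff, (pairs$dA + pairs$dB) / 2,
                       pairs$dA), , drop = FALSE]
  rownames(pairs) <- NULL
  list(hits = hits, pairs = pairs)
}

#' Assign the flanking regulatory sequence type of one locus
#'
#' When both a G-rich and a C-rich inverted-repeat call qualify, the one
#' with the lesser distance difference between the two ends wins (tie ->
#' G-IR). A locus with neither but with a selected concentric k-mer IR is
#' "other-IR"; otherwise "none".
#'
#' @param g_pairs,c_pairs Pair tables from [scan_flanks()] for the G-rich
#'   PWM and its reverse complement (best pair first).
#' @param has_other_ir Logical: locus carries a selected concentric k-mer
#'   IR (see [concentricity()]).
#' @return One-row data.frame: frs_type ("G-IR", "C-IR", "other-IR",
#'   "none"), dA, dB, dist_diff.
#' @export
assign_frs <- function(g_pairs, c_pairs, has_other_ir = FALSE) {
  has_g <- !is.null(g_pairs) && nrow(g_pairs) > 0
  has_c <- !is.null(c_pairs) && nrow(c_pairs) > 0
  pick <- function(type, p) {
    data.frame(frs_type = type, dA = p$dA[1], dB = p$dB[1],
               dist_diff = p$dist_diff[1], stringsAsFactors = FALSE)
  }
  if (has_g && has_c) {
    if (c_pairs$dist_diff[1] < g_pairs$dist_diff[1]) {
      pick("C-IR", c_pairs)
    } else {
      pick("G-IR", g_pairs)  # ties go to G-IR
    }
  } else if (has_g) {
    pick("G-IR", g_pairs)
  } else if (has_c) {
    pick("C-IR", c_pairs)
  } else if (has_other_ir) {
    data.frame(frs_type = "other-IR", dA = NA_integer_, dB = NA_integer_,
               dist_diff = NA_integer_, stringsAsFactors = FALSE)
  } else {
    data.frame(frs_type = "none", dA = NA_integer_, dB = NA_integer_,
               dist_diff = NA_integer_, stringsAsFactors = FALSE)
  }
}

#' FRS assignments for a catalogue of flank pairs
#'
#' Scans every locus's flanks with the G-rich PWM and its reverse
#' complement and assigns a type with [assign_frs()].
#'
#' @param flanks Output of [locus_flanks()].
#' @param pwm_g G-rich PWM from [build_pwm()].
#' @param threshold Similarity threshold (default 0.75).
#' @param max_dist_diff Maximum |dA - dB| (default 10).
#' @param other_ir_loci Locus ids carrying a selected concentric k-mer IR.
#' @return data.frame: locus_id, frs_type, dA, dB, dist_diff.
#' @export
frs_assignments <- function(flanks, pwm_g, threshold = 0.75,
                            max_dist_diff = 10, other_ir_loci = character(0)) {
  pwm_c <- revcomp_pwm(pwm_g)
  rows <- lapply(seq_len(nrow(flanks)), function(i) {
    g <- scan_flanks(flanks$left[i], flanks$right_rc[i], pwm_g, threshold,
                     max_dist_diff)$pairs
    cc <- scan_flanks(flanks$left[i], flanks$right_rc[i], pwm_c, threshold,
                      max_dist_diff)$pairs
    cbind(locus_id = flanks$locus_id[i],
          assign_frs(g, cc, flanks$locus_id[i] %in% other_ir_loci),
          stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), frs_type = character(0),
               dA = integer(0), dB = integer(0), dist_diff = integer(0))
  rownames(out) <- NULL
  out
}

#' Read a plain-text count matrix (JASPAR-like) as motif instances
#'
#' Reads a 4-row A/C/G/T count matrix and reconstitutes a PWM via
#' [build_pwm()]'s count path: the counts are used directly with the same
#' pseudocount and background treatment.
#'
#' @param path Path to a whitespace-separated file: 4 rows labelled
#'   A, C, G, T.
#' @param label Label for the PWM.
#' @inheritParams build_pwm
#' @return A `"pwm"` object.
#' @export
read_pfm <- function(path, label = "", pseudocount = 1,
                     background = c(0.25, 0.25, 0.25, 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  parts <- strsplit(trimws(lines), "[\\s\\[\\]]+", perl = TRUE)
  bases <- vapply(parts, `[`, character(1), 1)
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("PFM must have 4 rows labelled A, C, G, T", call. = FALSE)
  }
  counts <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  w <- ncol(counts)
  n <- sum(counts[, 1])
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
                 "/")
  mat <- log2(probs / background)
  structure(list(width = w, mat = mat,
                 s_min = sum(apply(mat, 2, min)),
                 s_max = sum(apply(mat, 2, max)),
                 label = label),
            class = "pwm")
}
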