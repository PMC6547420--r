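# Breakpoint refinement: candidate deletion intervals from a
# structural-variant caller are coarse; the base-exact ends are recovered
# from clipped-read (split-read) pileups by taking, within a window around
# each predicted end, the position with the highest clip count among those
# clearing a per-(strain, contig) mean-count threshold.

#' Clip-count threshold for a profile
#'
#' The arithmetic mean of clip counts, by default over positions with at
#' least one clipped read, used to remove false-positive pileup positions.
#' The all-positions variant divides by the contig length instead.
#'
#' @param profile data.frame with columns `pos`, `count` for one
#'   (strain, contig).
#' @param include_zeros If TRUE, average over every contig position
#'   (requires `contig_length`).
#' @param contig_length Contig length, only for `include_zeros = TRUE`.
#' @return The threshold (non-negative number).
#' @export
compute_clip_threshold <- function(profile, include_zeros = FALSE,
                                   contig_length = NULL) {
  counts <- profile$count[profile$count >= 1]
  if (length(counts) == 0) {
    stop("no clip evidence: profile has no position with count >= 1",
         call. = FALSE)
  }
  if (include_zeros) {
    if (is.null(contig_length)) {
      stop("contig_length required when include_zeros = TRUE", call. = FALSE)
    }
    sum(counts) / contig_length
  } else {
    mean(counts)
  }
}

#' Refine one predicted deletion end against a clip profile
#'
#' Within a `window`-bp window centred on the predicted position
#' (`predicted +/- window/2`, both sides inclusive), returns the position
#' with the highest clip count among those with count >= `threshold`.
#' Ties are broken by minimal distance to the prediction, then by the
#' smaller coordinate. Returns `NA` when no position passes.
#'
#' @param predicted Predicted end position (0-based).
#' @param profile data.frame with `pos`, `count` for the (strain, contig).
#' @param window Window width in bp (default 200, i.e. +/- 100).
#' @param threshold Minimum clip count (see [compute_clip_threshold()]).
#' @param all_maxima If TRUE, return every position tied at the maximal
#'   count (alternative boundaries) instead of the single tie-broken one.
#' @return Integer position(s), or `NA_integer_` when nothing passes.
#' @export
refine_end <- function(predicted, profile, window = 200, threshold,
                       all_maxima = FALSE) {
  stopifnot(window > 0)
  half <- window / 2
  keep <- abs(profile$pos - predicted) <= half & profile$count >= threshold
  if (!any(keep)) return(NA_integer_)
  pos <- profile$pos[keep]
  cnt <- profile$count[keep]
  mx <- max(cnt)
  at_max <- pos[cnt == mx]
  if (all_maxima) return(sort(at_max))
  at_max[order(abs(at_max - predicted), at_max)][1]
}

#' Refine a candidate table into base-exact deletion calls
#'
#' For every candidate interval, both ends are refined independently with
#' [refine_end()] against that strain's clip profile on that contig; a
#' candidate yields calls only when both ends refine and A < B. All
#' distinct surviving (A, B) combinations of tied maxima are kept as
#' alternative intra-strain forms. Dropped candidates are recorded with
#' reasons in the `"dropped"` attribute.
#'
#' @param candidates data.frame: strain, contig, start, end (0-based
#'   half-open predictions); extra columns (e.g. `locus_id`) are carried
#'   through.
#' @param clips data.frame: strain, contig, pos, count.
#' @param window Refinement window in bp (default 200).
#' @param thresholds Optional data.frame (strain, contig, threshold);
#'   computed per (strain, contig) with [compute_clip_threshold()] when
#'   omitted.
#' @return data.frame of refined calls: strain, contig, A, B, support_A,
#'   support_B (+ carried columns), with attribute `"dropped"`.
#' @export
refine_calls <- function(candidates, clips, window = 200, thresholds = NULL) {
  stopifnot_cols(candidates, c("strain", "contig", "start", "end"),
                 "candidates")
  stopifnot_cols(clips, c("strain", "contig", "pos", "count"), "clips")
  bad_strain <- setdiff(unique(candidates$strain), unique(clips$strain))
  if (length(bad_strain)) {
    stop("candidates reference strain(s) absent from clip profiles: ",
         paste(bad_strain, collapse = ", "), call. = FALSE)
  }
  bad_ctg <- setdiff(unique(candidates$contig), unique(clips$contig))
  if (length(bad_ctg)) {
    stop("candidates reference contig(s) absent from clip profiles: ",
         paste(bad_ctg, collapse = ", "), call. = FALSE)
  }
  key <- function(s, ctg) paste(s, ctg, sep = "\r")
  profs <- split(clips[c("pos", "count")], key(clips$strain, clips$contig))
  thr <- new.env(parent = emptyenv())
  if (!is.null(thresholds)) {
    for (i in seq_len(nrow(thresholds))) {
      assign(key(thresholds$strain[i], thresholds$contig[i]),
             thresholds$threshold[i], envir = thr)
    }
  }
  get_thr <- function(k) {
    if (!is.null(thresholds)) {
      if (!exists(k, envir = thr)) {
        stop("no threshold provided for profile ", gsub("\r", "/", k),
             call. = FALSE)
      }
      return(get(k, envir = thr))
    }
    if (!exists(k, envir = thr)) {
      assign(k, compute_clip_threshold(profs[[k]]), envir = thr)
    }
    get(k, envir = thr)
  }
  extra_cols <- setdiff(names(candidates),
                        c("strain", "contig", "start", "end", "uncertainty"))
  calls <- list()
  dropped <- list()
  for (i in seq_len(nrow(candidates))) {
    k <- key(candidates$strain[i], candidates$contig[i])
    prof <- profs[[k]]
    if (is.null(prof) || !any(prof$count >= 1)) {
      dropped[[length(dropped) + 1L]] <-
        cbind(candidates[i, ], reason = "no_evidence")
      next
    }
    th <- get_thr(k)
    As <- refine_end(candidates$start[i], prof, window, th, all_maxima = TRUE)
    Bs <- refine_end(candidates$end[i], prof, window, th, all_maxima = TRUE)
    if (all(is.na(As)) || all(is.na(Bs))) {
      reason <- if (all(is.na(As))) "no_A_support" else "no_B_support"
      dropped[[length(dropped) + 1L]] <- cbind(candidates[i, ], reason = reason)
      next
    }
    pairs <- expand.grid(A = As, B = Bs)
    pairs <- pairs[pairs$A < pairs$B, , drop = FALSE]
    if (nrow(pairs) == 0) {
      dropped[[length(dropped) + 1L]] <-
        cbind(candidates[i, ], reason = "crossed_ends")
      next
    }
    cnt_at <- function(p) prof$count[match(p, prof$pos)]
    df <- data.frame(
      strain = candidates$strain[i], contig = candidates$contig[i],
      A = as.integer(pairs$A), B = as.integer(pairs$B),
      support_A = cnt_at(pairs$A), support_B = cnt_at(pairs$B),
      stringsAsFactors = FALSE
    )
    for (cc in extra_cols) df[[cc]] <- candidates[[cc]][i]
    calls[[length(calls) + 1L]] <- df
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(strain = character(0), contig = character(0), A = integer(0),
               B = integer(0), support_A = integer(0), support_B = integer(0))
  rownames(out) <- NULL
  out <- unique(out)
  attr(out, "dropped") <- if (length(dropped)) {
    dd <- do.call(rbind, dropped); rownames(dd) <- NULL; dd
  } else NULL
  out
}
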