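# Independent brute-force oracles: deliberately naive re-implementations
# used only to cross-check the package's vectorized/indexed code paths.

# Exhaustive window scan for one end: max count, then min distance, then
# smaller coordinate.
brute_refine_end <- function(predicted, pos, count, window, threshold) {
  best <- NA_integer_
  best_cnt <- -Inf
  for (p in seq(predicted - window / 2, predicted + window / 2)) {
    i <- which(pos == p)
    if (length(i) == 0) next
    cnt <- count[i]
    if (cnt < threshold) next
    better <- cnt > best_cnt ||
      (cnt == best_cnt && abs(p - predicted) < abs(best - predicted)) ||
      (cnt == best_cnt && abs(p - predicted) == abs(best - predicted) &&
         p < best)
    if (better) {
      best <- p
      best_cnt <- cnt
    }
  }
  best
}

# Double loop over all (i, j) k-mer start pairs of the two processed
# flanks; identical strings at distance difference <= mdd.
brute_pair_search <- function(left, right_proc, k, mdd, right_junction_left) {
  W <- nchar(left)
  out <- list()
  for (i in 0:(W - k)) {
    kl <- substr(left, i + 1, i + k)
    if (grepl("N", kl, fixed = TRUE)) next
    dA <- W - i - k
    for (j in 0:(W - k)) {
      kr <- substr(right_proc, j + 1, j + k)
      if (grepl("N", kr, fixed = TRUE)) next
      if (kl != kr) next
      dB <- if (right_junction_left) j else W - j - k
      if (abs(dA - dB) <= mdd) {
        out[[length(out) + 1]] <- data.frame(kmer = kl, dA = dA, dB = dB,
                                             dist_diff = abs(dA - dB),
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kmer = character(0), dA = integer(0), dB = integer(0),
                      dist_diff = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$kmer, df$dA, df$dB), ]
  rownames(df) <- NULL
  df
}

brute_ir_pairs <- function(left, right_rc, k, mdd) {
  brute_pair_search(left, right_rc, k, mdd, right_junction_left = FALSE)
}

brute_dr_pairs <- function(left, right_rc, k, mdd) {
  right <- revcomp(right_rc)
  brute_pair_search(left, right, k, mdd, right_junction_left = TRUE)
}

# Direct matrix arithmetic for one window's min-max similarity (no reuse
# of pwm_similarity's indexing).
brute_similarity <- function(pwm, window) {
  v <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!v %in% c("A", "C", "G", "T"))) return(NA_real_)
  score <- 0
  smin <- 0
  smax <- 0
  for (j in seq_len(pwm$width)) {
    col <- pwm$mat[, j]
    score <- score + col[[v[j]]]
    smin <- smin + min(col)
    smax <- smax + max(col)
  }
  (score - smin) / (smax - smin)
}

# Exhaustive PWM pair scan over all window pairs of the two flanks.
brute_scan_pairs <- function(left, right_rc, pwm, threshold, mdd) {
  W <- nchar(left)
  k <- pwm$width
  out <- list()
  for (i in 0:(W - k)) {
    sl <- brute_similarity(pwm, substr(left, i + 1, i + k))
    if (is.na(sl) || sl < threshold) next
    for (j in 0:(W - k)) {
      sr <- brute_similarity(pwm, substr(right_rc, j + 1, j + k))
      if (is.na(sr) || sr < threshold) next
      dA <- W - i - k
      dB <- W - j - k
      if (abs(dA - dB) <= mdd) {
        out[[length(out) + 1]] <- data.frame(dA = dA, dB = dB,
                                             dist_diff = abs(dA - dB),
                                             sim_left = sl, sim_right = sr)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dA = integer(0), dB = integer(0), dist_diff = integer(0),
                      sim_left = numeric(0), sim_right = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$dA, df$dB), ]
  rownames(df) <- NULL
  df
}

# Connected components of the >=1-bp-overlap graph, naive O(n^2) BFS.
brute_cluster_partition <- function(A, B, contig = NULL) {
  n <- length(A)
  if (is.null(contig)) contig <- rep("c", n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- contig[i] == contig[j] && A[i] < B[j] && A[j] < B[i]
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Canonical form of a partition (for set-of-sets comparison): blocks
# sorted by their smallest member.
partition_sets <- function(labels) {
  sets <- unname(lapply(split(seq_along(labels), labels), sort))
  sets[order(vapply(sets, min, numeric(1)))]
}

random_dna <- function(n, gc = 0.25) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
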