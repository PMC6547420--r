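# Synthetic micronuclear (MIC) genome simulator: plants internal eliminated
# sequences (IESs) with junction microhomology and flanking inverted-repeat
# motifs into AT-rich contigs, then emulates per-strain deletion events and
# the evidence tables (candidate intervals + clipped-read pileups) that the
# downstream refinement pipeline consumes. All coordinates are 0-based,
# half-open [A, B).

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic MIC genome
#' generator. Defaults describe the package's reference study conditions:
#' two 1-Mb contigs at 25% GC carrying 200 planted IESs with a 10-bp
#' polypurine inverted repeat (IR) planted ~45 bp from each deletion end,
#' three wild-type strains with small boundary jitter and optional mutant
#' strains whose jitter is inflated at motif-marked loci.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (bp).
#' @param gc_fraction GC content of background sequence (MIC-like default 0.25).
#' @param n_ies Number of planted IESs genome-wide.
#' @param ies_length_range Integer pair, min/max planted IES length (bp);
#'   the minimum must be at least `100 + 2 * max(microhomology_length_range)`
#'   so planted loci survive the catalogue length filter.
#' @param ir_motif Motif planted as an inverted repeat in the flanks
#'   (string over ACGT), or `"none"`.
#' @param ir_distance Distance (bp) from each IES end to the IES-proximal
#'   base of its motif copy (0 = motif abuts the junction).
#' @param ir_jitter Uniform +/- jitter (bp) applied independently to the two
#'   motif distances.
#' @param ir_fraction Fraction of loci that receive the planted motif.
#' @param microhomology_length_range Integer pair >= 0; junction terminal
#'   direct repeat lengths.
#' @param strains Character vector of strain labels.
#' @param mut_strains Subset of `strains` treated as boundary-control
#'   mutants (inflated jitter at motif-marked loci).
#' @param boundary_jitter_wt,boundary_jitter_mut Uniform +/- jitter (bp) on
#'   each deletion end for wild-type strains, and for mutant strains at
#'   motif-marked loci.
#' @param intra_dup_fraction Fraction of loci given a second, distinct
#'   intra-strain deletion form (requires nonzero jitter).
#' @param skip_fraction Per-strain fraction of loci with no deletion event
#'   (emulates non-shared loci).
#' @param clip_noise_rate Per-position rate of background clipped-read noise.
#' @param clip_signal_mean Poisson mean of the clip-count signal at true
#'   deletion ends (a floor of 10 is added so signal clears the
#'   mean-threshold filter the way deep real pileups do).
#' @param candidate_displacement Maximum absolute displacement (bp) of the
#'   emulated structural-variant caller's interval ends from the true ends;
#'   must stay within half the refinement window.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_contigs = 2,
                       contig_length = 1e6,
                       gc_fraction = 0.25,
                       n_ies = 200,
                       ies_length_range = c(120L, 300L),
                       ir_motif = "AAAAAGGGGG",
                       ir_distance = 45,
                       ir_jitter = 3,
                       ir_fraction = 1,
                       microhomology_length_range = c(0L, 4L),
                       strains = c("CU427", "CU428", "BII"),
                       mut_strains = character(0),
                       boundary_jitter_wt = 5,
                       boundary_jitter_mut = 150,
                       intra_dup_fraction = 0.05,
                       skip_fraction = 0.02,
                       clip_noise_rate = 1e-3,
                       clip_signal_mean = 20,
                       candidate_displacement = 50,
                       seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    gc_fraction = gc_fraction,
    n_ies = as.integer(n_ies),
    ies_length_range = as.integer(ies_length_range),
    ir_motif = toupper(ir_motif),
    ir_distance = as.integer(ir_distance),
    ir_jitter = as.integer(ir_jitter),
    ir_fraction = ir_fraction,
    microhomology_length_range = as.integer(microhomology_length_range),
    strains = as.character(strains),
    mut_strains = as.character(mut_strains),
    boundary_jitter_wt = as.integer(boundary_jitter_wt),
    boundary_jitter_mut = as.integer(boundary_jitter_mut),
    intra_dup_fraction = intra_dup_fraction,
    skip_fraction = skip_fraction,
    clip_noise_rate = clip_noise_rate,
    clip_signal_mean = clip_signal_mean,
    candidate_displacement = as.integer(candidate_displacement),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_contigs >= 1, cfg$contig_length >= 1,
    cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
    cfg$n_ies >= 1,
    length(cfg$ies_length_range) == 2,
    cfg$ies_length_range[1] <= cfg$ies_length_range[2],
    length(cfg$microhomology_length_range) == 2,
    all(cfg$microhomology_length_range >= 0),
    cfg$ir_distance >= 0, cfg$ir_jitter >= 0,
    cfg$ir_fraction >= 0, cfg$ir_fraction <= 1,
    cfg$boundary_jitter_wt >= 0, cfg$boundary_jitter_mut >= 0,
    cfg$skip_fraction >= 0, cfg$skip_fraction < 1,
    cfg$intra_dup_fraction >= 0, cfg$intra_dup_fraction <= 1,
    cfg$clip_noise_rate >= 0, cfg$clip_noise_rate <= 1,
    length(cfg$strains) >= 1,
    all(cfg$mut_strains %in% cfg$strains)
  )
  mh_max <- cfg$microhomology_length_range[2]
  if (cfg$ies_length_range[1] < 100 + 2 * mh_max) {
    stop("ies_length_range minimum must be >= 100 + 2*max microhomology ",
         "so planted IESs survive the length filter", call. = FALSE)
  }
  if (has_motif(cfg)) {
    if (grepl("[^ACGT]", cfg$ir_motif)) {
      stop("ir_motif must be a string over {A,C,G,T} or \"none\"",
           call. = FALSE)
    }
    if (cfg$ir_distance - cfg$ir_jitter < max(1, mh_max)) {
      stop("ir_distance - ir_jitter must be >= max(1, microhomology max) ",
           "so planted motifs never collide with the junction", call. = FALSE)
    }
  }
  cfg
}

has_motif <- function(cfg) !identical(cfg$ir_motif, "NONE") &&
  !identical(cfg$ir_motif, "none") && nzchar(cfg$ir_motif)

# Exclusion margin around each planted IES: far enough from contig ends and
# neighbours that 100-bp flank extraction and 500-bp composition profiles
# never truncate or cross loci.
sim_margin <- function(cfg) {
  k <- if (has_motif(cfg)) nchar(cfg$ir_motif) else 0L
  as.integer(2 * (cfg$ir_distance + k + 500))
}

#' Generate a synthetic MIC genome with planted IESs
#'
#' Draws AT-rich contig sequences, plants non-overlapping IESs with
#' junction microhomology (the first `m` IES bases are copied to the
#' position immediately after the IES so left- and right-aligned deletion
#' representations are both valid), and plants the configured motif as an
#' inverted repeat in the two flanks. The emitted truth interval is
#' canonical (left-aligned): the base left of A always differs from the
#' base at B-1. Identical `(config, seed)` give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector of contig sequences)
#'   and `truth` (data.frame: locus_id, contig, true_A, true_B,
#'   planted_motif, left_motif_distance, right_motif_distance,
#'   microhomology).
#' @export
generate_mic_genome <- function(config) {
  cfg <- validate_sim_config(config)
  with_seed(derive_seed(cfg$seed, "genome"), {
    contigs <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
    # spread loci across contigs as evenly as possible
    per <- rep(cfg$n_ies %/% cfg$n_contigs, cfg$n_contigs)
    extra <- cfg$n_ies %% cfg$n_contigs
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    G <- sim_margin(cfg)
    p_base <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
                G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
    genome <- character(cfg$n_contigs)
    names(genome) <- contigs
    truth <- vector("list", cfg$n_contigs)
    for (ci in seq_len(cfg$n_contigs)) {
      k <- per[ci]
      vec <- sample(names(p_base), cfg$contig_length, replace = TRUE,
                    prob = p_base)
      if (k == 0) {
        genome[ci] <- paste(vec, collapse = "")
        truth[[ci]] <- NULL
        next
      }
      lens <- sample(seq(cfg$ies_length_range[1], cfg$ies_length_range[2]),
                     k, replace = TRUE)
      slack <- cfg$contig_length - sum(lens) - (k + 1L) * G
      if (slack < 0) {
        stop(sprintf(
          "infeasible packing: %d IESs (+margins of %d bp) exceed contig %s",
          k, G, contigs[ci]), call. = FALSE)
      }
      extras <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
      A <- integer(k)
      pos <- 0L
      for (i in seq_len(k)) {
        pos <- pos + G + extras[i]
        A[i] <- pos
        pos <- pos + lens[i]
      }
      B <- A + lens
      mh <- sample(seq(cfg$microhomology_length_range[1],
                       cfg$microhomology_length_range[2]),
                   k, replace = TRUE)
      motif_on <- if (has_motif(cfg)) {
        stats::runif(k) < cfg$ir_fraction
      } else rep(FALSE, k)
      dA <- dB <- rep(NA_integer_, k)
      if (any(motif_on)) {
        dA[motif_on] <- cfg$ir_distance + runif_int(sum(motif_on), cfg$ir_jitter)
        dB[motif_on] <- cfg$ir_distance + runif_int(sum(motif_on), cfg$ir_jitter)
      }
      mchars <- if (has_motif(cfg)) strsplit(cfg$ir_motif, "")[[1]] else NULL
      rchars <- if (has_motif(cfg)) strsplit(revcomp(cfg$ir_motif), "")[[1]] else NULL
      km <- length(mchars)
      mh_str <- character(k)
      for (i in seq_len(k)) {
        m <- mh[i]
        if (m > 0) {
          # terminal direct repeat: copy first m IES bases after the IES
          vec[(B[i] + 1L):(B[i] + m)] <- vec[(A[i] + 1L):(A[i] + m)]
          mh_str[i] <- paste(vec[(A[i] + 1L):(A[i] + m)], collapse = "")
        }
        if (motif_on[i]) {
          li <- A[i] - dA[i] - km  # 0-based motif start in left flank
          vec[(li + 1L):(li + km)] <- mchars
          ri <- B[i] + dB[i]
          vec[(ri + 1L):(ri + km)] <- rchars
        }
        # canonical-truth guard: base left of A must differ from base at B-1
        if (vec[A[i]] == vec[B[i]]) {
          vec[A[i]] <- sample(setdiff(c("A", "C", "G", "T"), vec[B[i]]), 1)
        }
      }
      genome[ci] <- paste(vec, collapse = "")
      truth[[ci]] <- data.frame(
        locus_id = sprintf("%s_%d", contigs[ci], A),
        contig = contigs[ci],
        true_A = A, true_B = B,
        planted_motif = ifelse(motif_on, cfg$ir_motif, NA_character_),
        left_motif_distance = dA, right_motif_distance = dB,
        microhomology = mh_str,
        stringsAsFactors = FALSE
      )
    }
    list(genome = genome, truth = do.call(rbind, truth))
  })
}

#' Generate one strain's deletion forms from the truth table
#'
#' Perturbs each planted locus's true ends by uniform integer jitter
#' (`boundary_jitter_wt`, or `boundary_jitter_mut` for mutant strains at
#' motif-marked loci), skips a configurable fraction of loci, and gives a
#' configurable fraction a second, distinct intra-strain form. Jitter that
#' would shrink a form below 100 bp is resampled. Each strain draws from
#' its own seed substream, so adding a strain leaves the others unchanged.
#'
#' @param truth Truth table from [generate_mic_genome()].
#' @param config The same [sim_config()].
#' @param strain One of `config$strains`.
#' @return data.frame of forms: locus_id, strain, contig, A, B.
#' @export
generate_strain_deletions <- function(truth, config, strain) {
  cfg <- validate_sim_config(config)
  if (!strain %in% cfg$strains) {
    stop(sprintf("unknown strain '%s'", strain), call. = FALSE)
  }
  is_mut <- strain %in% cfg$mut_strains
  with_seed(derive_seed(cfg$seed, "strain", strain), {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      if (cfg$skip_fraction > 0 && stats::runif(1) < cfg$skip_fraction) next
      j <- if (is_mut && !is.na(truth$planted_motif[i])) {
        cfg$boundary_jitter_mut
      } else {
        cfg$boundary_jitter_wt
      }
      draw_form <- function() {
        repeat {
          a <- truth$true_A[i] + runif_int(1, j)
          b <- truth$true_B[i] + runif_int(1, j)
          if (b - a >= 100 && a >= 0) return(c(a, b))
        }
      }
      f1 <- draw_form()
      forms <- list(f1)
      if (j > 0 && cfg$intra_dup_fraction > 0 &&
          stats::runif(1) < cfg$intra_dup_fraction) {
        for (try in 1:50) {
          f2 <- draw_form()
          if (!identical(f2, f1)) { forms <- c(forms, list(f2)); break }
        }
      }
      fm <- do.call(rbind, forms)
      out[[i]] <- data.frame(
        locus_id = truth$locus_id[i], strain = strain,
        contig = truth$contig[i],
        A = as.integer(fm[, 1]), B = as.integer(fm[, 2]),
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(locus_id = character(0), strain = character(0),
                        contig = character(0), A = integer(0), B = integer(0))
    }
    rownames(res) <- NULL
    res
  })
}

#' Emit candidate-interval and clip-profile evidence for deletion forms
#'
#' Emulates a structural-variant caller plus split-read pileups: each form
#' yields one candidate interval with ends displaced uniformly by up to
#' `candidate_displacement` bp, and per-strain clip profiles carry a
#' dominant count at each true form end (floor 10 plus Poisson signal) over
#' sparse low-count Poisson background at `clip_noise_rate`. The truth
#' linkage (`locus_id`) is retained in the candidate table for testing.
#'
#' @param forms data.frame of forms from [generate_strain_deletions()]
#'   (possibly several strains row-bound together).
#' @param config The same [sim_config()].
#' @return List with `candidates` (strain, contig, start, end, uncertainty,
#'   locus_id) and `clips` (strain, contig, pos, count).
#' @export
emit_evidence <- function(forms, config) {
  cfg <- validate_sim_config(config)
  if (nrow(forms) == 0) {
    return(list(
      candidates = data.frame(strain = character(0), contig = character(0),
                              start = integer(0), end = integer(0),
                              uncertainty = integer(0), locus_id = character(0)),
      clips = data.frame(strain = character(0), contig = character(0),
                         pos = integer(0), count = integer(0))
    ))
  }
  stopifnot(all(forms$A >= 0), all(forms$B <= cfg$contig_length))
  with_seed(derive_seed(cfg$seed, "evidence"), {
    d <- cfg$candidate_displacement
    candidates <- data.frame(
      strain = forms$strain, contig = forms$contig,
      start = forms$A + runif_int(nrow(forms), d),
      end = forms$B + runif_int(nrow(forms), d),
      uncertainty = d, locus_id = forms$locus_id,
      stringsAsFactors = FALSE
    )
    clip_list <- list()
    for (s in unique(forms$strain)) {
      fs <- forms[forms$strain == s, ]
      for (ctg in unique(fs$contig)) {
        fc <- fs[fs$contig == ctg, ]
        sig_pos <- sort(unique(c(fc$A, fc$B)))
        sig_cnt <- 10L + stats::rpois(length(sig_pos), cfg$clip_signal_mean)
        noise <- NULL
        if (cfg$clip_noise_rate > 0) {
          n_noise <- stats::rpois(1, cfg$contig_length * cfg$clip_noise_rate)
          if (n_noise > 0) {
            np <- sample.int(cfg$contig_length, min(n_noise, cfg$contig_length)) - 1L
            np <- setdiff(np, sig_pos)
            if (length(np)) {
              noise <- data.frame(pos = np,
                                  count = 1L + stats::rpois(length(np), 0.5))
            }
          }
        }
        df <- data.frame(pos = sig_pos, count = sig_cnt)
        if (!is.null(noise)) df <- rbind(df, noise)
        df <- df[order(df$pos), ]
        clip_list[[paste(s, ctg)]] <- data.frame(
          strain = s, contig = ctg, pos = df$pos, count = df$count,
          stringsAsFactors = FALSE
        )
      }
    }
    clips <- do.call(rbind, clip_list)
    rownames(clips) <- NULL
    list(candidates = candidates, clips = clips)
  })
}

#' Reconstruct the somatic (MAC) product of a set of deletions
#'
#' Removes non-overlapping 0-based half-open intervals from a contig
#' sequence and rejoins the retained pieces.
#'
#' @param seq Contig sequence (single string).
#' @param A,B Integer vectors of interval starts/ends (0-based half-open).
#' @return The rejoined product string.
#' @export
mac_product <- function(seq, A, B) {
  if (length(A) == 0) return(seq)
  o <- order(A)
  A <- A[o]; B <- B[o]
  stopifnot(all(B > A), all(A[-1] >= B[-length(B)]))
  keep_starts <- c(0L, B)
  keep_ends <- c(A, nchar(seq))
  paste(substring(seq, keep_starts + 1L, keep_ends), collapse = "")
}

#' Match catalogued loci back to the simulator's truth table
#'
#' Assigns each catalogued locus the planted truth record whose interval
#' its span overlaps (planted loci are pairwise distant, so the match is
#' unique).
#'
#' @param loci Locus table with contig, span_start, span_end (see
#'   [locus_table()]).
#' @param truth Truth table from [generate_mic_genome()].
#' @return `loci` with an added `truth_id` column (NA when unmatched).
#' @export
match_loci_to_truth <- function(loci, truth) {
  loci$truth_id <- NA_character_
  for (ctg in unique(loci$contig)) {
    li <- which(loci$contig == ctg)
    ti <- which(truth$contig == ctg)
    if (!length(li) || !length(ti)) next
    q <- IRanges::IRanges(start = loci$span_start[li] + 1L,
                          end = loci$span_end[li])
    s <- IRanges::IRanges(start = truth$true_A[ti] + 1L,
                          end = truth$true_B[ti])
    ov <- IRanges::findOverlaps(q, s, select = "first")
    loci$truth_id[li] <- truth$locus_id[ti][ov]
  }
  loci
}
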