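# Mutant-vs-wild-type boundary contrast: flags loci whose boundary
# variation is tightly controlled in wild-type strains but inflates in
# boundary-control-mutant (e.g. LIA3-knockout) strains, tabulates the
# enrichment of G-/C-rich inverted repeats among flagged loci, and surveys
# alternative-boundary loci for multiple flanking regulatory sequences.

#' Flag mutant-affected loci
#'
#' A locus (considered only when it has at least one form in every
#' wild-type and every mutant strain) is flagged when its wild-type
#' maximum boundary variation is at most `wt_max_variation` bp and pooling
#' the mutant forms raises the maximum variation by at least
#' `min_increase` bp (strictly more with `strict_increase = TRUE`).
#'
#' @param forms Output of [cluster_forms()] covering both strain sets.
#' @param wt_strains,mut_strains Disjoint non-empty strain label sets.
#' @param wt_max_variation Wild-type variation cap in bp (default 100;
#'   a stringent survey uses 20).
#' @param min_increase Minimum variation increase in bp (default 100).
#' @param strict_increase If TRUE require increase > `min_increase`
#'   instead of >=.
#' @return data.frame over considered loci: locus_id, wt_variation,
#'   pooled_variation, increase, flagged.
#' @export
lia3_affected <- function(forms, wt_strains, mut_strains,
                          wt_max_variation = 100, min_increase = 100,
                          strict_increase = FALSE) {
  stopifnot(length(wt_strains) >= 1, length(mut_strains) >= 1,
            length(intersect(wt_strains, mut_strains)) == 0)
  all_strains <- c(wt_strains, mut_strains)
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  considered <- names(sp)[vapply(sp, function(i) {
    all(all_strains %in% forms$strain[i])
  }, logical(1))]
  if (!length(considered)) {
    return(data.frame(locus_id = character(0), wt_variation = integer(0),
                      pooled_variation = integer(0), increase = integer(0),
                      flagged = logical(0)))
  }
  out <- do.call(rbind, lapply(considered, function(id) {
    i <- sp[[id]]
    wt <- i[forms$strain[i] %in% wt_strains]
    pooled <- i[forms$strain[i] %in% all_strains]
    vw <- max_boundary_variation(forms$A[wt], forms$B[wt])
    vp <- max_boundary_variation(forms$A[pooled], forms$B[pooled])
    data.frame(locus_id = id, wt_variation = vw, pooled_variation = vp,
               increase = vp - vw, stringsAsFactors = FALSE)
  }))
  pass_inc <- if (strict_increase) out$increase > min_increase else
    out$increase >= min_increase
  out$flagged <- out$wt_variation <= wt_max_variation & pass_inc
  rownames(out) <- NULL
  out
}

#' Inverted-repeat enrichment table for flagged vs background loci
#'
#' Per strain, and aggregated over "at least one strain" and "all
#' strains", counts flagged loci assigned a G-rich or C-rich IR, their
#' total (the per-strain assignment makes the two classes disjoint) and
#' the percentage of the flagged set; likewise for the background set.
#' Percentages are rounded half-up at 2 decimals; empty sets give NA.
#'
#' @param assignments data.frame (strain, locus_id, frs_type) of per-strain
#'   FRS assignments (see [frs_assignments()]).
#' @param flagged_ids,background_ids Disjoint locus id sets.
#' @param strains Strain labels to report (default those present).
#' @return data.frame: strain, n_gir, n_cir, total, percent,
#'   bg_gir, bg_cir, bg_total, bg_percent.
#' @export
enrichment_table <- function(assignments, flagged_ids, background_ids,
                             strains = NULL) {
  stopifnot_cols(assignments, c("strain", "locus_id", "frs_type"),
                 "assignments")
  if (is.null(strains)) strains <- sort(unique(assignments$strain))
  count_set <- function(ids) {
    g_by <- lapply(strains, function(s) {
      a <- assignments[assignments$strain == s & assignments$locus_id %in% ids, ]
      a$locus_id[a$frs_type == "G-IR"]
    })
    c_by <- lapply(strains, function(s) {
      a <- assignments[assignments$strain == s & assignments$locus_id %in% ids, ]
      a$locus_id[a$frs_type == "C-IR"]
    })
    per_strain <- lapply(seq_along(strains), function(si) {
      g <- g_by[[si]]; cc <- c_by[[si]]
      c(n_gir = length(g), n_cir = length(cc),
        total = length(union(g, cc)))
    })
    any_g <- unique(unlist(g_by)); any_c <- unique(unlist(c_by))
    all_g <- Reduce(intersect, g_by); all_c <- Reduce(intersect, c_by)
    list(per_strain = per_strain,
         at_least_one = c(n_gir = length(any_g), n_cir = length(any_c),
                          total = length(union(any_g, any_c))),
         all_strains = c(n_gir = length(all_g), n_cir = length(all_c),
                         total = length(union(all_g, all_c))))
  }
  fl <- count_set(flagged_ids)
  bg <- count_set(background_ids)
  rows <- c(strains, "at least one strain", "all strains")
  take <- function(res, i) {
    if (i <= length(strains)) res$per_strain[[i]]
    else if (i == length(strains) + 1) res$at_least_one
    else res$all_strains
  }
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    f <- take(fl, i); b <- take(bg, i)
    fc <- enrichment_cells(f[["n_gir"]], f[["n_cir"]], length(flagged_ids),
                           total = f[["total"]])
    bc <- enrichment_cells(b[["n_gir"]], b[["n_cir"]], length(background_ids),
                           total = b[["total"]])
    data.frame(strain = rows[i],
               n_gir = f[["n_gir"]], n_cir = f[["n_cir"]],
               total = fc$total, percent = fc$percent,
               bg_gir = b[["n_gir"]], bg_cir = b[["n_cir"]],
               bg_total = bc$total, bg_percent = bc$percent,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Enrichment-cell arithmetic
#'
#' The reporting arithmetic behind one [enrichment_table()] row, exposed
#' so published count tables can be fed through the same code path: total
#' (G + C counts, disjoint by assignment, unless a union total is given)
#' and the percentage of the denominator, half-up at 2 decimals (NA for a
#' zero denominator).
#'
#' @param n_gir,n_cir Locus counts with G-rich / C-rich IR.
#' @param denominator Size of the locus set the percentage refers to.
#' @param total Optional pre-computed union total overriding
#'   `n_gir + n_cir`.
#' @return data.frame: total, percent.
#' @export
enrichment_cells <- function(n_gir, n_cir, denominator, total = NULL) {
  if (is.null(total)) total <- n_gir + n_cir
  percent <- if (denominator == 0) NA_real_ else
    round_half_up(100 * total / denominator, 2)
  data.frame(total = total, percent = percent)
}

#' Survey alternative boundaries for multiple flanking regulatory sequences
#'
#' For each locus with more than `min_variation` bp of boundary variation
#' and an assigned G- or C-rich IR, every distinct boundary form's own
#' flanks are scanned for the same IR type; a form qualifies when it has a
#' pair whose left distance lies within `max_dist_diff` bp of the locus's
#' modal (median) distance. A locus is "multiple-FRS" when at least two
#' distinct boundary forms each have their own qualifying pair.
#'
#' @param forms Output of [cluster_forms()].
#' @param genome Named character vector of contig sequences.
#' @param assignments Per-locus FRS assignments (locus_id, frs_type) from
#'   [frs_assignments()] for the reference strain.
#' @param pwm_g G-rich PWM.
#' @param threshold Similarity threshold (default 0.75).
#' @param max_dist_diff Distance tolerance in bp (default 10).
#' @param min_variation Only loci with variation strictly above this are
#'   surveyed (default 20).
#' @param W Flank width (default 100).
#' @return data.frame: locus_id, frs_type, n_forms_distinct,
#'   n_forms_with_frs, multiple_frs.
#' @export
multiple_frs_survey <- function(forms, genome, assignments, pwm_g,
                                threshold = 0.75, max_dist_diff = 10,
                                min_variation = 20, W = 100) {
  pwms <- list("G-IR" = pwm_g, "C-IR" = revcomp_pwm(pwm_g))
  var_tab <- locus_variation(forms)
  cand <- assignments[assignments$frs_type %in% names(pwms), , drop = FALSE]
  cand <- cand[cand$locus_id %in%
                 var_tab$locus_id[var_tab$max_variation > min_variation], ,
               drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(locus_id = character(0), frs_type = character(0),
                      n_forms_distinct = integer(0),
                      n_forms_with_frs = integer(0),
                      multiple_frs = logical(0)))
  }
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(ci) {
    id <- cand$locus_id[ci]
    pwm <- pwms[[cand$frs_type[ci]]]
    i <- sp[[id]]
    uf <- unique(forms[i, c("contig", "A", "B")])
    best <- lapply(seq_len(nrow(uf)), function(fi) {
      fp <- extract_flanks(uf$A[fi], uf$B[fi], genome[[uf$contig[fi]]], W)
      if (is.null(fp)) return(NULL)
      p <- scan_flanks(fp$left, fp$right_rc, pwm, threshold, max_dist_diff)$pairs
      if (nrow(p) == 0) NULL else p[1, ]
    })
    has <- !vapply(best, is.null, logical(1))
    dAs <- vapply(best[has], function(p) p$dA, numeric(1))
    n_q <- 0L
    if (length(dAs)) {
      modal <- stats::median(dAs)
      n_q <- sum(abs(dAs - modal) <= max_dist_diff)
    }
    data.frame(locus_id = id, frs_type = cand$frs_type[ci],
               n_forms_distinct = nrow(uf), n_forms_with_frs = n_q,
               multiple_frs = nrow(uf) >= 2 && n_q >= 2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Percentage of loci with low variation at at least one end
#'
#' Per locus, the maximum spread of A positions and of B positions are
#' computed separately; the locus qualifies when either is at most
#' `cutoff` bp.
#'
#' @param forms Output of [cluster_forms()].
#' @param cutoff Per-end variation cutoff in bp (default 20).
#' @return Percentage (half-up, 2 decimals).
#' @export
pct_low_variation_one_end <- function(forms, cutoff = 20) {
  sp <- split(seq_len(nrow(forms)), forms$locus_id)
  ok <- vapply(sp, function(i) {
    ev <- end_variation(forms$A[i], forms$B[i])
    min(ev) <= cutoff
  }, logical(1))
  round_half_up(100 * mean(ok), 2)
}

#' Headline summary statistics from class percentages
#'
#' Derived quantities reported over the variation-class histograms: the
#' percentage of loci with at most 20 bp variation (sum of the "0" and
#' 1-to-20-bp class percentages) per strain set, and the difference of the
#' ">100" class percentages between the mutant and wild-type sets. Inputs
#' are named percent vectors keyed by class label; a pre-combined "1-20"
#' entry is accepted in place of "1-10" + "11-20". All values half-up at
#' 2 decimals.
#'
#' @param wt_percents,mut_percents Named numeric vectors of class
#'   percentages (e.g. from [class_histogram()]: `setNames(h$percent,
#'   h$class_label)`).
#' @return data.frame: le20_wt, le20_mut, over100_wt, over100_mut,
#'   over100_diff.
#' @export
headline_stats <- function(wt_percents, mut_percents) {
  le20 <- function(p) {
    keys <- intersect(c("0", "1-10", "11-20", "1-20"), names(p))
    round_half_up(sum(p[keys]), 2)
  }
  over100 <- function(p) {
    if (!">100" %in% names(p)) NA_real_ else unname(p[">100"])
  }
  data.frame(
    le20_wt = le20(wt_percents),
    le20_mut = le20(mut_percents),
    over100_wt = over100(wt_percents),
    over100_mut = over100(mut_percents),
    over100_diff = round_half_up(over100(mut_percents) - over100(wt_percents),
                                 2)
  )
}
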