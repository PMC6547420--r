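# Mutant contrast: affected-locus flagging, enrichment tables,
# multiple-FRS survey and headline arithmetic.

make_locus <- function(id, per_strain) {
  # per_strain: named list strain -> matrix/list of c(A, B) forms
  do.call(rbind, lapply(names(per_strain), function(s) {
    m <- per_strain[[s]]
    if (!is.matrix(m)) m <- matrix(m, ncol = 2, byrow = TRUE)
    data.frame(locus_id = id, strain = s, contig = "c1",
               A = m[, 1], B = m[, 2], stringsAsFactors = FALSE)
  }))
}

test_that("affected-locus flagging applies the variation-increase rule", {
  wt <- c("w1", "w2")
  mut <- c("m1", "m2")
  forms <- rbind(
    # WT maxvar 15, pooled 140 -> flagged (increase 125 >= 100)
    make_locus("L1", list(w1 = c(1000, 1500), w2 = c(1010, 1505),
                          m1 = c(1000, 1640), m2 = c(1005, 1500))),
    # WT maxvar 150 -> excluded by the WT cap
    make_locus("L2", list(w1 = c(5000, 5500), w2 = c(5100, 5550),
                          m1 = c(5000, 5800), m2 = c(5000, 5500))),
    # quiet locus, no mutant effect
    make_locus("L3", list(w1 = c(9000, 9300), w2 = c(9001, 9300),
                          m1 = c(9000, 9301), m2 = c(9002, 9299))),
    # missing mutant strain -> not considered
    make_locus("L4", list(w1 = c(12000, 12300), w2 = c(12000, 12300),
                          m1 = c(12000, 12450)))
  )
  res <- lia3_affected(forms, wt, mut)
  expect_setequal(res$locus_id, c("L1", "L2", "L3"))
  expect_true(res$flagged[res$locus_id == "L1"])
  expect_equal(res$wt_variation[res$locus_id == "L1"], 15)
  expect_equal(res$increase[res$locus_id == "L1"], 130)
  expect_false(res$flagged[res$locus_id == "L2"])
  expect_false(res$flagged[res$locus_id == "L3"])
  # pooled variation never below WT variation
  expect_true(all(res$pooled_variation >= res$wt_variation))
  # decreasing min_increase never unflags
  res50 <- lia3_affected(forms, wt, mut, min_increase = 50)
  expect_true(all(res$flagged <= res50$flagged[match(res$locus_id,
                                                     res50$locus_id)]))
  # strict comparison drops an exact-increase locus
  forms_exact <- make_locus("E1", list(w1 = c(100, 400), w2 = c(100, 400),
                                       m1 = c(100, 500), m2 = c(100, 400)))
  expect_true(lia3_affected(forms_exact, wt, mut)$flagged)
  expect_false(lia3_affected(forms_exact, wt, mut,
                             strict_increase = TRUE)$flagged)
  expect_error(lia3_affected(forms, "w1", "w1"), "disjoint|length")
})

test_that("flagging recovers the planted mutant-affected set on synthetic data", {
  cfg <- small_config(n_contigs = 2, contig_length = 6e5, n_ies = 120,
                      ir_fraction = 0.5, boundary_jitter_wt = 8,
                      boundary_jitter_mut = 150,
                      strains = c("CU427", "CU428", "BII",
                                  "3-1", "4-1", "27-2"),
                      mut_strains = c("3-1", "4-1", "27-2"),
                      intra_dup_fraction = 0.05, seed = 55)
  sim <- generate_mic_genome(cfg)
  forms <- cluster_forms(do.call(rbind, lapply(cfg$strains, function(s) {
    generate_strain_deletions(sim$truth, cfg, s)
  })))
  res <- lia3_affected(forms, c("CU427", "CU428", "BII"),
                       c("3-1", "4-1", "27-2"))
  # map catalogue loci to planted truth by overlap
  loci <- match_loci_to_truth(locus_table(forms), sim$truth)
  truth_affected <- sim$truth$locus_id[!is.na(sim$truth$planted_motif)]
  flagged_truth <- loci$truth_id[match(res$locus_id[res$flagged],
                                       loci$locus_id)]
  unflagged_truth <- loci$truth_id[match(res$locus_id[!res$flagged],
                                         loci$locus_id)]
  sens <- mean(flagged_truth %in% truth_affected)
  spec <- mean(!(unflagged_truth %in% truth_affected))
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("enrichment table counts are internally consistent", {
  strains <- c("s1", "s2")
  asg <- rbind(
    data.frame(strain = "s1", locus_id = c("L1", "L2", "L3", "L4"),
               frs_type = c("G-IR", "C-IR", "none", "G-IR")),
    data.frame(strain = "s2", locus_id = c("L1", "L2", "L3", "L4"),
               frs_type = c("G-IR", "none", "C-IR", "C-IR"))
  )
  et <- enrichment_table(asg, flagged_ids = c("L1", "L2", "L3"),
                         background_ids = "L4", strains = strains)
  s1 <- et[et$strain == "s1", ]
  expect_equal(s1$n_gir, 1)
  expect_equal(s1$n_cir, 1)
  expect_equal(s1$total, 2)
  expect_equal(s1$percent, round_half_up(100 * 2 / 3, 2))
  one <- et[et$strain == "at least one strain", ]
  expect_equal(one$n_gir, 1)   # L1 in either strain
  expect_equal(one$n_cir, 2)   # L2 (s1), L3 (s2)
  expect_equal(one$total, 3)
  all3 <- et[et$strain == "all strains", ]
  expect_equal(all3$n_gir, 1)  # L1 in both
  expect_equal(all3$n_cir, 0)
  # per-strain totals equal G + C (classes disjoint by assignment)
  expect_true(all(et$total[1:2] == et$n_gir[1:2] + et$n_cir[1:2]))
  # zero background hits give 0.00, empty sets give NA
  et0 <- enrichment_table(asg, flagged_ids = c("L1", "L2"),
                          background_ids = "L3", strains = "s1")
  expect_equal(et0$bg_percent[1], 0)
  etNA <- enrichment_table(asg, flagged_ids = c("L1", "L2"),
                           background_ids = character(0), strains = "s1")
  expect_true(is.na(etNA$bg_percent[1]))
})

test_that("multiple-FRS survey detects alternative boundaries with own IR pairs", {
  set.seed(807)
  pwm <- build_pwm(gpwm_instances(), label = "G-rich")
  motif <- "AAAAAGGGGG"
  k <- nchar(motif)
  # construct a contig with one IES having two alternative left boundaries
  # 300 bp apart, each with its own motif copy ~45 bp upstream, plus a
  # shared right boundary with one motif copy downstream
  bg <- function(n) random_dna(n, gc = 0)
  A1 <- 500; A2 <- 800; B <- 1400
  vec <- strsplit(bg(2000), "")[[1]]
  place <- function(vec, pos0, s) {
    vec[(pos0 + 1):(pos0 + nchar(s))] <- strsplit(s, "")[[1]]
    vec
  }
  vec <- place(vec, A1 - 45 - k, motif)
  vec <- place(vec, A2 - 45 - k, motif)
  vec <- place(vec, B + 45, revcomp(motif))
  genome <- c(c1 = paste(vec, collapse = ""))
  forms <- cluster_forms(data.frame(
    strain = c("CU427", "CU428"), contig = "c1",
    A = c(A1, A2), B = c(B, B)
  ))
  asg <- data.frame(locus_id = forms$locus_id[1], frs_type = "G-IR")
  surv <- multiple_frs_survey(forms, genome, asg, pwm)
  expect_equal(nrow(surv), 1)
  expect_true(surv$multiple_frs)
  expect_equal(surv$n_forms_with_frs, 2)
  # one shared FRS pair only: high variation but not multiple-FRS
  forms2 <- cluster_forms(data.frame(
    strain = c("CU427", "CU428"), contig = "c1",
    A = c(A1, A1 - 200), B = c(B, B)
  ))
  surv2 <- multiple_frs_survey(forms2, genome,
                               data.frame(locus_id = forms2$locus_id[1],
                                          frs_type = "G-IR"), pwm)
  expect_false(surv2$multiple_frs[1])
})

test_that("headline arithmetic reproduces derived percentage sums and differences", {
  wt <- c("0" = 14.71, "1-20" = 38.87, ">100" = 27.79)
  mut <- c("0" = 10, "1-10" = 20, "11-20" = 8.87, ">100" = 38.87)
  hs <- headline_stats(wt, mut)
  expect_equal(hs$le20_wt, 53.58)
  expect_equal(hs$le20_mut, 38.87)
  expect_equal(hs$over100_diff, 11.08)
  # identical strain sets difference is zero
  expect_equal(headline_stats(wt, wt)$over100_diff, 0)
})

test_that("per-end variation percentage counts loci quiet at one or both ends", {
  forms <- rbind(
    make_locus("L1", list(s1 = c(100, 400), s2 = c(100, 700))),   # A quiet
    make_locus("L2", list(s1 = c(1000, 1400), s2 = c(1300, 1700))),# both loud
    make_locus("L3", list(s1 = c(5000, 5300)))                     # single form
  )
  expect_equal(pct_low_variation_one_end(forms, cutoff = 20),
               round_half_up(100 * 2 / 3, 2))
})
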