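# Flank extraction, inverted/direct-repeat pair search, concentricity and
# composition profiles.

test_that("flank extraction reverse-complements the downstream side", {
  #          0123456789...
  seq <- paste0("AAAAAGATTC", "CCCCCCCCCC", "AGGTAAAAAA")
  fp <- extract_flanks(10, 20, seq, W = 5)
  expect_equal(fp$left, "GATTC")
  expect_equal(fp$right_rc, revcomp("AGGTA"))
  expect_equal(fp$right_rc, "TACCT")
  # truncated flank -> exclusion
  expect_null(extract_flanks(3, 20, seq, W = 5))
  expect_null(extract_flanks(10, 27, seq, W = 5))
  # palindromic context: right_rc equals left
  pal <- paste0("GAATTC", "TTTTTTTTTT", "GAATTC")
  fp2 <- extract_flanks(6, 16, pal, W = 6)
  expect_equal(fp2$left, fp2$right_rc)
})

test_that("locus flanks use the reference strain's smallest form and log exclusions", {
  genome <- c(c1 = random_dna(1000))
  forms <- cluster_forms(data.frame(
    strain = c("CU427", "CU427", "CU428", "CU428"),
    contig = "c1",
    A = c(300, 310, 305, 30),
    B = c(500, 505, 500, 160)
  ))
  fl <- locus_flanks(forms, genome, W = 100, reference = "CU427")
  expect_equal(nrow(fl), 1)
  expect_equal(fl$A, 300)  # lexicographically smallest CU427 form
  excl <- attr(fl, "excluded")
  expect_equal(excl$reason, "no_reference_form")
  # near-edge locus excluded when the reference strain holds it
  fl2 <- locus_flanks(forms, genome, W = 100, reference = "CU428")
  expect_true("flank_crosses_contig_end" %in% attr(fl2, "excluded")$reason)
})

test_that("inverted-repeat pair search applies the distance-difference filter", {
  set.seed(701)
  W <- 100
  base_l <- random_dna(W, gc = 0)  # AT-only background cannot spell TACCG
  base_r <- random_dna(W, gc = 0)
  plant <- function(s, kmer, d) {
    # place so the IES-proximal (last) base sits d bp from the junction
    i0 <- W - d - nchar(kmer)
    paste0(substr(s, 1, i0), kmer, substr(s, i0 + nchar(kmer) + 1, W))
  }
  l <- plant(base_l, "TACCG", 62)
  r <- plant(base_r, "TACCG", 58)
  hits <- find_ir_pairs(l, r, k = 5, max_dist_diff = 10)
  h <- hits[hits$kmer == "TACCG", ]
  expect_equal(nrow(h), 1)
  expect_equal(h$dA, 62)
  expect_equal(h$dB, 58)
  expect_equal(h$dist_diff, 4)
  # difference 12 exceeds the filter
  r2 <- plant(base_r, "TACCG", 74)
  hits2 <- find_ir_pairs(l, r2, k = 5, max_dist_diff = 10)
  expect_equal(nrow(hits2[hits2$kmer == "TACCG", ]), 0)
})

test_that("direct-repeat search uses genome orientation and excludes inverted matches", {
  set.seed(702)
  W <- 60
  l <- paste0(random_dna(W - 45 - 5, gc = 0), "AAGGT", random_dna(45, gc = 0))
  # right flank in genome orientation carries AAGGT at distance 45 from B
  right_fwd <- paste0(random_dna(45, gc = 0), "AAGGT", random_dna(W - 50, gc = 0))
  r_rc <- revcomp(right_fwd)
  dr <- find_dr_pairs(l, r_rc, k = 5, max_dist_diff = 10)
  h <- dr[dr$kmer == "AAGGT", ]
  expect_equal(h$dA, 45)
  expect_equal(h$dB, 45)
  # the same non-palindromic arrangement is not an IR hit at those positions
  ir <- find_ir_pairs(l, r_rc, k = 5, max_dist_diff = 10)
  expect_equal(nrow(ir[ir$kmer == "AAGGT", ]), 0)
})

test_that("pair search matches the exhaustive double-loop oracle", {
  set.seed(703)
  for (rep in 1:200) {
    W <- sample(c(30, 60, 100), 1)
    l <- random_dna(W, gc = 0.25)
    r <- random_dna(W, gc = 0.25)
    mdd <- sample(c(5, 10, 20), 1)
    expect_equal(find_ir_pairs(l, r, 5, mdd), brute_ir_pairs(l, r, 5, mdd),
                 info = sprintf("IR rep %d", rep))
    expect_equal(find_dr_pairs(l, r, 5, mdd), brute_dr_pairs(l, r, 5, mdd),
                 info = sprintf("DR rep %d", rep))
  }
})

test_that("reverse-complementing the contig mirrors the IR hit multiset", {
  set.seed(704)
  seq <- random_dna(600)
  A <- 200; B <- 380
  fp <- extract_flanks(A, B, seq, W = 100)
  # on the reverse-complemented contig the roles of the two ends swap
  rcseq <- revcomp(seq)
  n <- nchar(seq)
  A2 <- n - B; B2 <- n - A
  fp2 <- extract_flanks(A2, B2, rcseq, W = 100)
  h1 <- find_ir_pairs(fp$left, fp$right_rc, 5, 100)
  h2 <- find_ir_pairs(fp2$left, fp2$right_rc, 5, 100)
  key <- function(h) sort(paste(h$kmer, pmin(h$dA, h$dB), pmax(h$dA, h$dB)))
  expect_equal(key(h1), key(h2))
})

test_that("concentricity selects tight, recurrent motif groups by IQR and count", {
  hits <- data.frame(kmer = "TACCG", dA = c(60, 62, 62, 65),
                     dB = c(60, 62, 62, 65))
  st <- concentricity(hits)
  expect_equal(st$iqr, 1.25)  # q75 62.75 - q25 61.5, type-7 quantiles
  expect_equal(st$count, 4)
  expect_true(st$selected)
  # count 2 fails the count threshold despite IQR 0
  st2 <- concentricity(data.frame(kmer = "AAAAA", dA = c(50, 50)))
  expect_equal(st2$iqr, 0)
  expect_false(st2$selected)
  # identical distances give IQR 0
  st3 <- concentricity(data.frame(kmer = "CCCCC", dA = rep(44, 6)))
  expect_equal(st3$iqr, 0)
  expect_true(st3$selected)
})

test_that("core grouping pools k-mers (N matches any base) and recomputes stats", {
  hits <- data.frame(
    kmer = c("TATAA", "TATAA", "ATATA", "TATAT", "GGGGG"),
    dA = c(60, 61, 62, 63, 10)
  )
  g <- group_by_core(hits, "TATA")
  expect_equal(g$count, 4)  # GGGGG does not contain the core
  expect_equal(g$iqr,
               unname(diff(stats::quantile(c(60, 61, 62, 63), c(.25, .75),
                                           type = 7))))
  # N wildcard core
  hits2 <- data.frame(kmer = c("TACCGT", "TACCAT", "TACCCC"),
                      dA = c(45, 46, 44))
  g2 <- group_by_core(hits2, "TACCNT")
  expect_equal(g2$count, 2)  # TACCCC does not match TACC[ACGT]T
  # empty pool
  g3 <- group_by_core(hits, "CCCGG")
  expect_equal(g3$count, 0)
  expect_false(g3$selected)
})

test_that("composition profiles are normalized and localize planted base runs", {
  # all-A flanks around a fixed IES
  seq <- paste0(strrep("A", 50), strrep("C", 120), strrep("A", 50))
  prof <- composition_profile(
    data.frame(contig = "c1", A = 50, B = 170),
    c(c1 = seq), span = 50, align = "A-end")
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "T")]) - 1) < 1e-12))
  expect_true(all(prof$A[prof$position >= 0] == 1))  # flank side all A
  expect_true(all(prof$C[prof$position < 0] == 1))   # IES side all C
  # planted G-run at flank distances 40-60 peaks at exactly those positions
  cfg <- small_config(n_ies = 30, ir_motif = strrep("G", 21),
                      ir_distance = 40, ir_jitter = 0, seed = 41)
  sim <- generate_mic_genome(cfg)
  prof2 <- composition_profile(
    data.frame(contig = sim$truth$contig, A = sim$truth$true_A,
               B = sim$truth$true_B),
    sim$genome, span = 100, align = "both")
  flank <- prof2[prof2$position >= 0, ]
  in_run <- flank$position >= 40 & flank$position <= 60
  expect_true(all(flank$G[in_run] > 0.9))
  expect_lt(max(flank$G[!in_run]), 0.6)
  expect_true(all(abs(rowSums(prof2[, c("A", "C", "G", "T")]) - 1) < 1e-12))
})

test_that("planted pentamer IR group is recovered from truth flanks", {
  cfg <- small_config(n_ies = 25, ir_motif = "TACCG", ir_distance = 45,
                      ir_jitter = 3, boundary_jitter_wt = 0, seed = 43)
  sim <- generate_mic_genome(cfg)
  forms <- cluster_forms(do.call(rbind, lapply(cfg$strains, function(s) {
    generate_strain_deletions(sim$truth, cfg, s)
  })))
  fl <- locus_flanks(forms, sim$genome, W = 100, reference = "CU427")
  hits <- repeat_hits(fl, k = 5, max_dist_diff = 10, orientation = "IR")
  st <- concentricity(hits)
  row <- st[st$kmer == "TACCG", ]
  expect_true(row$selected)
  expect_lte(abs(row$median_dA - 45), 3)
})
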