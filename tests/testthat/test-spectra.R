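test_that("pairwise distances follow the codon-level trichotomy", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0L)
  expect_equal(pairwise_distance("ACGT", "ACGA"), 1L)
  # gap columns excluded by default, counted when indels are included
  expect_equal(pairwise_distance("AC-T", "ACGT"), 0L)
  expect_equal(pairwise_distance("AC-T", "ACGT", indels_included = TRUE), 1L)
  # CTT vs TTA: both Leu, two nucleotide changes -> 1 synonymous, 0 aa
  ref <- paste0("CTTGGG")
  tb <- locus_table("t", c(ref, "TTAGGG"), c(1, 1), ref_b = ref,
                    coding_intervals = data.frame(start = 0, end = 6,
                                                  strand = "+", frame = 0,
                                                  hypothetical = 0))
  tb$designated_cds <- 1L
  ca1 <- codon_align("CTTGGG", tb)
  ca2 <- codon_align("TTAGGG", tb)
  expect_equal(pairwise_distance(ca1, ca2, "synonymous"), 1L)
  expect_equal(pairwise_distance(ca1, ca2, "amino_acid"), 0L)
  # excluding indels never increases a distance
  set.seed(1)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 30, TRUE), collapse = "")
    expect_lte(pairwise_distance(a, b),
               pairwise_distance(a, b, indels_included = TRUE))
  }
})

test_that("weighted spectra enumerate ordered pairs and average over loci", {
  one <- locus_table("a", "AAAA", 10)
  sp1 <- weighted_distance_spectrum(list(one))
  expect_equal(sp1$distance, 0L)
  expect_equal(sp1$mass, 1)
  # two alleles at 0.5/0.5 and distance 4: ordered pairs put half the mass
  # at zero (self-pairs) and half at 4
  two <- locus_table("b", c("AAAATTTT", "TTTTTTTT"), c(5, 5))
  sp2 <- weighted_distance_spectrum(list(two))
  expect_equal(sp2$distance, c(0L, 4L))
  expect_equal(sp2$mass, c(0.5, 0.5))
  # excluding self-pairs moves all mass to 4
  sp2b <- weighted_distance_spectrum(list(two), include_self = FALSE)
  expect_equal(sp2b$mass[sp2b$distance == 4], 1)
  # invariance under allele re-ordering and equal-weight locus averaging
  two_r <- locus_table("b2", c("TTTTTTTT", "AAAATTTT"), c(5, 5))
  expect_equal(weighted_distance_spectrum(list(two_r))$mass, sp2$mass)
  both <- weighted_distance_spectrum(list(one, two))
  expect_equal(both$mass[both$distance == 0], (1 + 0.5) / 2)
  expect_equal(sum(both$mass), 1, tolerance = 1e-9)
})

test_that("geometric null has the closed form mass and normalization", {
  g <- geometric_null(8)
  expect_equal(g$mass[g$distance == 0], 1 / 9, tolerance = 1e-9)
  expect_equal(sum(g$mass), 1, tolerance = 1e-9)
  expect_equal(spectrum_mean(g), 8, tolerance = 1e-6)
  g0 <- geometric_null(1e-9)
  expect_equal(g0$mass[g0$distance == 0], 1, tolerance = 1e-6)
})

test_that("main cloud boundary is inclusive at the threshold", {
  L <- 400
  top <- paste(rep("A", L), collapse = "")
  at40 <- paste(c(rep("C", 40), rep("A", 360)), collapse = "")
  at41 <- paste(c(rep("C", 41), rep("A", 359)), collapse = "")
  tb <- locus_table("m", c(top, at40, at41), c(10, 2, 1))
  mc <- main_cloud_partition(tb, 0.10)
  expect_equal(mc$labels, c("main_cloud", "main_cloud", "outlier"))
  expect_equal(mc$labels[1], "main_cloud")  # most abundant always inside
  expect_equal(mc$frac_reads, 12 / 13)
})

test_that("triangles classify by the A/B/C precedence rules", {
  L <- 100
  m <- paste(rep("A", L), collapse = "")
  flip <- function(k) paste(c(rep("G", k), rep("A", L - k)), collapse = "")
  # type A: ref_b close, ref_a far
  tbA <- locus_table("A", m, 10, ref_b = flip(1), ref_a = flip(20))
  expect_equal(classify_triangle(tbA)$type, "A")
  # type B: both close
  tbB <- locus_table("B", m, 10, ref_b = flip(2), ref_a = flip(3))
  expect_equal(classify_triangle(tbB)$type, "B")
  # type C: both far, far apart, with alleles near each reference
  ref_b <- flip(20)
  ref_a <- paste(c(rep("A", 80), rep("T", 20)), collapse = "")
  near_b <- paste(c(rep("G", 19), rep("A", 81)), collapse = "")
  near_a <- paste(c(rep("A", 81), rep("T", 19)), collapse = "")
  tbC <- locus_table("C", c(m, near_b, near_a), c(10, 2, 2),
                     ref_b = ref_b, ref_a = ref_a)
  expect_equal(classify_triangle(tbC)$type, "C")
  # same but no allele near ref_a: other
  tbO <- locus_table("O", c(m, near_b), c(10, 2), ref_b = ref_b,
                     ref_a = ref_a)
  expect_equal(classify_triangle(tbO)$type, "other")
  expect_error(classify_triangle(locus_table("x", m, 1, ref_b = m)),
               "both references")
})

test_that("complete-linkage OTU clustering matches a brute-force oracle", {
  expect_equal(cluster_otus(rep("ACGT", 3), 0.03), rep(1L, 3))
  g1 <- paste(rep("A", 100), collapse = "")
  g2 <- paste(c(rep("T", 10), rep("A", 90)), collapse = "")
  expect_equal(length(unique(cluster_otus(c(g1, g1, g2, g2), 0.03))), 2)
  set.seed(8)
  for (rep in 1:5) {
    seqs <- vapply(1:8, function(i)
      paste(sample(c("A", "C"), 40, TRUE, prob = c(0.8, 0.2)),
            collapse = ""), "")
    k <- length(seqs)
    dm <- matrix(0, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      dm[i, j] <- dm[j, i] <- pairwise_distance(seqs[i], seqs[j]) / 40
    ours <- cluster_otus(seqs, 0.15)
    oracle <- brute_complete_linkage(dm, 0.15)
    # same partition up to label permutation
    expect_equal(outer(ours, ours, "=="), outer(oracle, oracle, "=="))
  }
})

test_that("nearest-allele statistics match self-comparison expectations", {
  set.seed(9)
  tbs <- list()
  for (i in 1:3) {
    cfg <- sim_config(n = 200, L = 100, theta = 0.03)
    tbs[[sprintf("l%d", i)]] <- simulate_locus(cfg, 200,
                                               locus_id = sprintf("l%d", i))
  }
  # reads that are copies of table alleles: all distances zero
  reads <- do.call(rbind, lapply(names(tbs), function(loc)
    data.frame(sequence = tbs[[loc]]$alleles$sequence[1:3], locus_id = loc)))
  out <- nearest_allele_stats(reads, tbs, n_null = 2000, seed = 10)
  expect_true(all(out$distances == 0))
  expect_equal(length(out$matched_freq), nrow(reads))
  # a read one SNP from its source has distance 1
  r1 <- data.frame(sequence = mutate_at(tbs$l1$alleles$sequence[1], 5,
                                        setdiff(c("A", "C", "G", "T"),
                                                substr(tbs$l1$alleles$sequence[1],
                                                       5, 5))[1]),
                   locus_id = "l1")
  out1 <- nearest_allele_stats(r1, tbs, n_null = 0)
  expect_equal(out1$distances, 1L)
  # unknown locus counted and skipped
  out2 <- nearest_allele_stats(data.frame(sequence = "AAAA",
                                          locus_id = "nope"), tbs,
                               n_null = 0)
  expect_equal(out2$n_skipped, 1)
  # frequency-weighted second sample matches the resampling null closely:
  # compare mean matched frequency against the null mean
  set.seed(11)
  second <- do.call(rbind, lapply(names(tbs), function(loc) {
    tb <- tbs[[loc]]
    idx <- sample.int(nrow(tb$alleles), 100, TRUE, prob = tb$alleles$frequency)
    data.frame(sequence = tb$alleles$sequence[idx], locus_id = loc)
  }))
  out3 <- nearest_allele_stats(second, tbs, n_null = 5000, seed = 12)
  m_obs <- mean(out3$matched_freq)
  null_mean <- sum(out3$null_spectrum$fraction *
                     10^(out3$null_spectrum$bin / 2 + 0.25))
  expect_lt(abs(log(m_obs / null_mean)), log(2))
})

test_that("exact-match curve reduces correctly in the degenerate limits and
           covers model-generated data", {
  one <- locus_table("u", paste(rep("A", 50), collapse = ""), 100)
  # c = 1, single allele at frequency 1, m >= 1 reads: match certain
  rd <- data.frame(sequence = one$alleles$sequence, locus_id = "u")
  out <- exact_match_curve(list(u = one), rd, match_rate_c = 1)
  expect_equal(out$expected, 1)
  out0 <- exact_match_curve(list(u = one), rd, match_rate_c = 0)
  expect_equal(out0$expected, 0)
  # synthetic reads generated by the model fall inside the 99% band
  set.seed(13)
  tbs <- list()
  for (i in 1:4) {
    cfg <- sim_config(n = 300, L = 60, theta = 0.05)
    tbs[[sprintf("g%d", i)]] <- simulate_locus(cfg, 300,
                                               locus_id = sprintf("g%d", i))
  }
  c_true <- 0.34
  reads <- do.call(rbind, lapply(names(tbs), function(loc) {
    tb <- tbs[[loc]]
    m <- 60
    idx <- sample.int(nrow(tb$alleles), m, TRUE, prob = tb$alleles$frequency)
    keep <- runif(m) < c_true
    seqs <- vapply(seq_len(m), function(k) {
      if (keep[k]) tb$alleles$sequence[idx[k]] else
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    }, "")
    data.frame(sequence = seqs, locus_id = loc)
  }))
  # a fraction c of the m = 60 external reads per locus is identical with the
  # population (frequency-weighted), the rest unrelated: the model's premise
  curve <- exact_match_curve(tbs, reads, match_rate_c = c_true)
  inside <- curve$observed >= curve$lower & curve$observed <= curve$upper
  expect_gte(mean(inside), 0.7)
})
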