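mk_pair_alignment <- function(codons1, codons2) {
  structure(list(ref_codons = codons1, allele_codons = codons2,
                 n_codons = length(codons1)), class = "codon_alignment")
}

test_that("codon difference trichotomy is at the codon level", {
  expect_equal(count_codon_differences(
    mk_pair_alignment("TTT", "TTC"))[c("n_syn", "n_nonsyn")],
    list(n_syn = 1L, n_nonsyn = 0L))
  expect_equal(count_codon_differences(
    mk_pair_alignment("TTT", "TTA"))$n_nonsyn, 1L)
  # CTT vs TTA: Leu vs Leu with two nucleotide changes is ONE synonymous
  # codon difference, not two SNP-level events
  out <- count_codon_differences(mk_pair_alignment("CTT", "TTA"))
  expect_equal(out$n_syn, 1L)
  expect_equal(out$n_nonsyn, 0L)
  # gapped codons skipped
  out2 <- count_codon_differences(mk_pair_alignment(c("TTT", NA), c("TTC", NA)))
  expect_equal(out2$n_codons, 1L)
  # interior stop in the reference warns and is skipped
  expect_warning(out3 <- count_codon_differences(
    mk_pair_alignment(c("TAA", "TTT"), c("TAA", "TTT"))), "stop")
  expect_equal(out3$n_codons, 1L)
})

test_that("internal dn/ds normalization matches brute-force error enumeration", {
  em <- error_model(total_sub_rate = 0.63, L = 400)
  # uniform lambda on a single TTT codon: of the 9 single-base outcomes only
  # TTC (pos 3, T->C) is synonymous, so E_syn/E_total = 1/9 at first order
  lam_u <- matrix(1e-3, 4, 4, dimnames = list(c("A","C","G","T"),
                                              c("A","C","G","T")))
  diag(lam_u) <- 0
  E <- micdiv:::expected_error_differences("TTT", lam_u)
  first_order <- c(E_syn = 1e-3, E_ns = 8e-3)
  expect_equal(E[["E_syn"]] / sum(E), 1 / 9, tolerance = 0.02)
  expect_equal(E[["E_syn"]], first_order[["E_syn"]], tolerance = 0.01)
  # identical sequences: both zero, ratio missing
  ca <- mk_pair_alignment(c("TTT", "ATG"), c("TTT", "ATG"))
  res <- dnds_internal(ca, em)
  expect_equal(res$d_s, 0)
  expect_equal(res$d_n, 0)
  expect_true(is.na(res$ratio))
  # scaling invariance: doubling lambda halves d_s and d_n
  ca2 <- mk_pair_alignment(c("TTT", "ATG", "CTT"), c("TTC", "ATG", "CTT"))
  em2 <- em; em2$lambda_sub <- em$lambda_sub * 2
  r1 <- dnds_internal(ca2, em)
  r2 <- dnds_internal(ca2, em2)
  # exact at first order; the two-error term leaves a relative residual of
  # order the per-site rate (~1e-4)
  expect_equal(r2$d_s, r1$d_s / 2, tolerance = 1e-3)
})

test_that("counting-method dn/ds recovers generator rates on long pairs", {
  expect_equal(dnds_counting(mk_pair_alignment("TTT", "TTT"))$d_s, 0)
  # all-synonymous toy pair (padded with identical codons so the synonymous
  # proportion stays below the Jukes-Cantor saturation bound)
  toy <- dnds_counting(mk_pair_alignment(c("TTT", "GGG", rep("CCC", 6)),
                                         c("TTC", "GGA", rep("CCC", 6))))
  expect_equal(toy$d_n, 0)
  expect_gt(toy$d_s, 0)
  # long pair at known per-site rates: generate codon pairs by applying
  # synonymous or non-synonymous single-base changes at fixed probabilities
  set.seed(51)
  codons <- names(genetic_code())[genetic_code() != "*"]
  c1 <- sample(codons, 12000, TRUE)
  c2 <- vapply(c1, function(cd) {
    if (runif(1) < 0.35) {
      vars <- micdiv:::single_base_variants(cd)
      syn <- translate_codon(vars$codon) == translate_codon(cd)
      pick_syn <- runif(1) < 0.5 && any(syn)
      pool <- if (pick_syn) vars$codon[syn] else vars$codon[!syn]
      if (length(pool) == 0) pool <- vars$codon
      sample(pool, 1)
    } else cd
  }, "", USE.NAMES = FALSE)
  res <- dnds_counting(mk_pair_alignment(c1, c2))
  # cross-check against direct proportion bookkeeping (JC-corrected)
  cnt <- micdiv:::ng_counts_from_alignment(mk_pair_alignment(c1, c2))
  expect_equal(res$d_s, -3 / 4 * log(1 - 4 * (cnt[["Sd"]] / cnt[["S"]]) / 3),
               tolerance = 1e-9)
  expect_equal(res$d_n, -3 / 4 * log(1 - 4 * (cnt[["Nd"]] / cnt[["N"]]) / 3),
               tolerance = 1e-9)
})

test_that("per-locus weighted dn/ds matches hand enumeration on a toy table", {
  ref <- "TTTGGGCTT"
  ci <- data.frame(start = 0, end = 9, strand = "+", frame = 0,
                   hypothetical = 0)
  # allele 2 has one synonymous difference (TTT->TTC)
  tb <- locus_table("w", c(ref, "TTCGGGCTT"), c(6, 4), ref_b = ref,
                    coding_intervals = ci)
  tb$designated_cds <- 1L
  out <- per_locus_weighted_dnds(tb)
  pair <- dnds_counting(codon_align("TTCGGGCTT", tb))
  w <- 2 * 0.6 * 0.4
  expect_equal(out$d_s, w * pair$d_s / (0.6^2 + 0.4^2 + w), tolerance = 1e-9)
  expect_equal(out$d_n, 0)
  # monomorphic locus: both zero
  mono <- locus_table("m", ref, 10, ref_b = ref, coding_intervals = ci)
  mono$designated_cds <- 1L
  outm <- per_locus_weighted_dnds(mono)
  expect_equal(c(outm$d_n, outm$d_s), c(0, 0))
})

test_that("concatenation pools counts rather than averaging ratios", {
  a1 <- mk_pair_alignment(c("TTT", "GGG"), c("TTC", "GGG"))  # 1 syn
  a2 <- mk_pair_alignment(c("TTT", "GGG"), c("TTT", "GGC"))  # 1 syn? GGG->GGC syn
  a3 <- mk_pair_alignment(c("TTT", "GGG"), c("CTT", "GGG"))  # 1 nonsyn (F->L)
  single <- concatenated_mle(list(a1))
  direct <- dnds_counting(a1)
  expect_equal(single$d_s, direct$d_s)
  pooled <- concatenated_mle(list(a1, a3))
  cnt1 <- micdiv:::ng_counts_from_alignment(a1)
  cnt3 <- micdiv:::ng_counts_from_alignment(a3)
  p_s <- (cnt1[["Sd"]] + cnt3[["Sd"]]) / (cnt1[["S"]] + cnt3[["S"]])
  expect_equal(pooled$d_s, -3 / 4 * log(1 - 4 * p_s / 3), tolerance = 1e-9)
})

test_that("binned dn vs ds curves use the stated window and count schemes", {
  pts <- data.frame(d_s = c(0.01, 0.02, 0.04, 0.06, 0.07, 0.09),
                    d_n = c(1, 2, 3, 4, 5, 6) / 100)
  w <- binned_dn_vs_ds(pts, "window_0.05")
  expect_equal(w$mean_dn, c(mean(c(1, 2, 3) / 100), mean(c(4, 5, 6) / 100)))
  expect_equal(w$n_points, c(3L, 3L))
  flat <- data.frame(d_s = runif(90), d_n = 0.5)
  expect_true(all(binned_dn_vs_ds(flat, "window_0.05")$mean_dn == 0.5))
  eq <- binned_dn_vs_ds(data.frame(d_s = runif(90), d_n = runif(90)),
                        "equal_count_30")
  expect_equal(nrow(eq), 30)
  expect_true(all(eq$n_points == 3))
})

test_that("least-squares fits recover exact generating lines", {
  x <- seq(0.05, 1, by = 0.05)
  f1 <- suppressWarnings(
    fit_dn_ds(data.frame(d_s = x, d_n = 0.1 * x), through_origin = TRUE))
  expect_equal(f1$slope, 0.1, tolerance = 1e-12)
  expect_equal(diff(f1$ci), 0, tolerance = 1e-9)
  f2 <- suppressWarnings(
    fit_dn_ds(data.frame(d_s = x, d_n = 0.104 * x - 0.007),
              through_origin = FALSE))
  expect_equal(f2$slope, 0.104, tolerance = 1e-9)
  expect_equal(f2$intercept, -0.007, tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_dn_ds(data.frame(d_s = c(1, 1), d_n = c(1, 2)),
                         through_origin = FALSE), "degenerate")
})

test_that("single-time fit: closed-form MLE, merging invariance, degenerate
           inputs", {
  fit <- poisson_single_time_fit(c(3, 1), c(10, 10))
  expect_equal(fit$theta_hat, 0.2)
  expect_equal(sum(fit$expected$expected), 2, tolerance = 1e-9)
  expect_equal(poisson_single_time_fit(c(0, 0), c(5, 5))$theta_hat, 0)
  expect_error(poisson_single_time_fit(numeric(0), numeric(0)), "units")
  # sufficiency: merging loci leaves the MLE unchanged
  f1 <- poisson_single_time_fit(c(2, 4, 6), c(10, 20, 30))
  f2 <- poisson_single_time_fit(12, 60)
  expect_equal(f1$theta_hat, f2$theta_hat)
})

test_that("divergence groups split at the inclusive 0.3 boundary", {
  out <- split_divergence_groups(c(0.29, 0.3, 0.31))
  expect_equal(out$labels, c("low", "high", "high"))
  set.seed(52)
  ds <- c(rnorm(207, 0.15, 0.03), rnorm(1726, 0.7, 0.1))
  out2 <- split_divergence_groups(pmax(ds, 0.01))
  expect_equal(out2$n_low + out2$n_high, 1933)
})

test_that("GC bias bookkeeping adds up and reproduces the odds arithmetic", {
  # identical genomes: everything conserved, equal biases
  b <- rep(c("A", "C", "G", "T"), 25)
  same <- gc_bias_bookkeeping(b, b)
  expect_equal(same$n_conserved, 100)
  expect_equal(same$bias_first, same$bias_second)
  # class additivity on random pairs, gaps tallied
  set.seed(53)
  g1 <- sample(c("A", "C", "G", "T", "-"), 5000, TRUE,
               prob = c(0.15, 0.35, 0.35, 0.14, 0.01))
  g2 <- g1
  flip <- sample(5000, 800)
  g2[flip] <- sample(c("A", "C", "G", "T"), 800, TRUE)
  out <- gc_bias_bookkeeping(g1, g2)
  expect_equal(out$n_conserved + out$n_tv_ACTG + out$n_transitions +
                 out$n_tv_AGCT, out$n_total)
  expect_equal(out$n_total + out$n_skipped, 5000)
  # polarized odds identity: bias = GC / (total - GC)
  expect_equal(out$bias_first, out$gc_first / (out$n_total - out$gc_first))
})
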