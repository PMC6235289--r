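# a small hand-checkable coding locus: 2 codons CDS + 3 intergenic sites
# codons: CTT (Leu) TTT (Phe); alleles vary at specific sites
sfs_fixture <- function() {
  ref <- "CTTTTTAAA"
  ci <- data.frame(start = 0L, end = 6L, strand = "+", frame = 0L,
                   hypothetical = 0L)
  # allele 2: CTC (Leu) at codon 1 (third-site transition T->C)
  # allele 3: TTA (Leu) at codon 1 (first-site C->T, synonymous L pair;
  #           third-site T->A)
  # allele 4: intergenic SNP A->G at site 7
  seqs <- c("CTTTTTAAA", "CTCTTTAAA", "TTATTTAAA", "CTTTTTGAA")
  tb <- locus_table("sfx", seqs, c(60, 20, 10, 10), ref_b = ref,
                    coding_intervals = ci)
  tb$designated_cds <- 1L
  tb
}

test_that("site classification follows the codon-position rules by hand
           enumeration", {
  cl <- classify_sites(sfs_fixture())
  expect_s3_class(cl, "site_classification")
  # classes partition the reference columns
  expect_equal(nrow(cl), 9)
  expect_true(all(cl$class %in% c("syn_third", "syn_first_LRS",
                                  "nonsyn_second", "intergenic", "excluded")))
  # codon 1 most common aa is Leu (90 reads) -> first site is syn_first_LRS
  expect_equal(cl$class[1], "syn_first_LRS")
  expect_equal(cl$class[2], "nonsyn_second")
  expect_equal(cl$class[3], "syn_third")
  # codon 2 is Phe: first site excluded, third site synonymous
  expect_equal(cl$class[4], "excluded")
  expect_equal(cl$class[6], "syn_third")
  # intergenic tail
  expect_equal(cl$class[7:9], rep("intergenic", 3))
  # all four alleles code Leu at codon 1 (CTT/CTC/TTA/CTT), so every read
  # qualifies: third-site counts T 70, C 20, A 10 over R = 100
  expect_equal(unname(unlist(cl[3, c("A", "C", "G", "T")])),
               c(10L, 20L, 0L, 70L))
  expect_equal(cl$R[3], 100L)
  # first-site counts: C 90, T 10
  expect_equal(unname(unlist(cl[1, c("A", "C", "G", "T")])),
               c(0L, 90L, 0L, 10L))
  # intergenic counts use all alleles
  expect_equal(unname(unlist(cl[7, c("A", "C", "G", "T")])),
               c(90L, 0L, 10L, 0L))
  # a codon whose most common amino acid is Met gets no third site
  ref2 <- "ATGAAA"
  tb2 <- locus_table("m", ref2, 10, ref_b = ref2,
                     coding_intervals = data.frame(start = 0, end = 6,
                                                   strand = "+", frame = 0,
                                                   hypothetical = 0))
  tb2$designated_cds <- 1L
  cl2 <- classify_sites(tb2)
  expect_equal(cl2$class[3], "excluded")
  # a fully intergenic locus classifies every column intergenic
  tb3 <- locus_table("ig", "ACGTACGT", 5, ref_b = "ACGTACGT")
  expect_true(all(classify_sites(tb3)$class == "intergenic"))
})

test_that("transition dimorphs are polarized and filtered as specified", {
  cl <- classify_sites(sfs_fixture())
  dm <- extract_transition_dimorphs(cl)
  # site 1 (C/T transition, f_AT = 10/100), site 7 (A/G, f_AT = 0.9);
  # site 3 carries three variants and is dropped
  expect_equal(sort(dm$position), c(1L, 7L))
  expect_equal(dm$f_AT[dm$position == 1], 0.1)
  expect_equal(dm$f_AT[dm$position == 7], 0.9)
  expect_equal(unname(attr(dm, "dropped")["multi_variant"]), 1L)
  mk_cl <- function(A, C, G, T) {
    df <- data.frame(position = 1L, class = "syn_third", A = A, C = C,
                     G = G, T = T, R = A + C + G + T)
    class(df) <- c("site_classification", class(df))
    df
  }
  expect_equal(extract_transition_dimorphs(mk_cl(90, 0, 10, 0))$f_AT, 0.9)
  expect_equal(nrow(extract_transition_dimorphs(mk_cl(50, 50, 0, 0))), 0)
  expect_equal(nrow(extract_transition_dimorphs(mk_cl(70, 10, 20, 0))), 0)
  d1 <- attr(extract_transition_dimorphs(mk_cl(50, 50, 0, 0)), "dropped")
  expect_equal(unname(d1["transversion"]), 1L)
})

test_that("ell binning puts f = 1/2 in the [0,1) bin and matches a hand
           density", {
  dm <- data.frame(f_AT = 0.5, R = 100)
  out <- sfs_binned(dm, "ell_sfs", site_depths = rep(100, 10))
  expect_equal(nrow(out), 1)
  expect_equal(out$bin_low, 0)
  # hand arithmetic: one SNP / (bin width in f x eligible sites)
  width <- 1 / (1 + exp(-1)) - 0.5
  expect_equal(out$value, 1 / (width * 10))
  # empty input gives an empty spectrum
  expect_equal(nrow(sfs_binned(dm[0, ], "ell_sfs")), 0)
  # histogram binning normalizes to 1
  dm2 <- data.frame(f_AT = c(0.5, 0.6, 0.9), R = 100)
  h <- sfs_binned(dm2, "ell_histogram")
  expect_equal(sum(h$value), 1)
  # depth conditioning idempotence: dropping sites too shallow for a bin
  # leaves that bin unchanged
  dm3 <- data.frame(f_AT = c(0.01, 0.5), R = c(500, 500))
  depths <- c(rep(500, 50), rep(20, 50))
  full <- sfs_binned(dm3, "ell_sfs", site_depths = depths)
  lowbin <- full[full$bin_low == min(full$bin_low), ]
  eligible_only <- sfs_binned(dm3, "ell_sfs",
                              site_depths = depths[depths > 1 / 0.0179])
  low2 <- eligible_only[eligible_only$bin_low == min(eligible_only$bin_low), ]
  expect_equal(lowbin$value, low2$value)
})

test_that("beta-binomial expectation: uniform at theta = 1, normalized,
           symmetric, with the theta/2 plateau at ell = 0", {
  expect_equal(beta_binomial_pmf(1, 3), rep(1 / 4, 4), tolerance = 1e-12)
  for (theta in c(0.03, 0.3, 2)) for (R in c(5, 40)) {
    p <- beta_binomial_pmf(theta, R)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p, rev(p), tolerance = 1e-9)
  }
  # small theta continuous limit: the ell-density near ell = 0 is theta/2
  theta <- 0.02
  exp_sfs <- neutral_sfs_expectation(theta, rep(2000, 1000), "ell_sfs")
  mid <- exp_sfs$value[exp_sfs$bin_low == 0]
  # density per site in f, times the Jacobian f(1-f) at f ~ 1/2 gives the
  # ell-density; compare the binned value against theta/2 / (f(1-f)) ~ 4*theta/2
  f_mid <- (exp_sfs$f_low[exp_sfs$bin_low == 0] +
              exp_sfs$f_high[exp_sfs$bin_low == 0]) / 2
  ell_density <- mid * f_mid * (1 - f_mid)
  expect_equal(ell_density, theta / 2, tolerance = 0.1)
})

test_that("ns/syn ratio divides matched minor-frequency bins", {
  dm <- data.frame(f_AT = c(0.01, 0.3, 0.6, 0.995), R = 1000)
  syn <- sfs_binned(dm, "minor_pow2", site_depths = rep(1000, 100))
  ratio1 <- ns_syn_ratio(syn, syn)
  expect_true(all(ratio1$ratio[!is.na(ratio1$ratio)] == 1))
  # ns counts a quarter of syn per bin, site-normalized
  ns <- syn; ns$value <- syn$value / 4
  expect_true(all(ns_syn_ratio(ns, syn)$ratio[!is.na(syn$value) &
                                                syn$value > 0] == 0.25))
  bad <- sfs_binned(dm, "ell_sfs")
  expect_error(ns_syn_ratio(bad, syn), "minor_pow2")
})

test_that("deleterious SFS is a pointwise exponential suppression", {
  f <- c(0.001, 0.01, 0.1, 0.5, 0.9)
  neutral <- deleterious_sfs(selection_params(0, 1e5), 0.02, f)
  expect_equal(neutral, 0.02 / (2 * f * (1 - f)))
  sel <- deleterious_sfs(selection_params(1e-3, 1e5), 0.02, f)
  expect_equal(sel[3] / neutral[3], exp(-10), tolerance = 1e-9)
  # monotone in s at every frequency
  s_grid <- c(0, 1e-5, 1e-4, 1e-3)
  dens <- vapply(s_grid, function(s)
    deleterious_sfs(selection_params(s, 1e5), 0.02, f), numeric(length(f)))
  for (r in seq_along(f)) expect_true(all(diff(dens[r, ]) <= 0))
})

test_that("fixed-site composition reflects GC-biased equilibrium", {
  # all-A intergenic locus: everything AT
  tb <- locus_table("allA", paste(rep("A", 50), collapse = ""), 10,
                    ref_b = paste(rep("A", 50), collapse = ""))
  fc <- fixed_site_composition(classify_sites(tb))
  expect_equal(fc$n_AT, 50)
  expect_equal(fc$n_GC, 0)
  # beta = 2.5 biased simulation: GC fraction near 2.5/3.5 at equilibrium
  set.seed(31)
  n_at <- n_gc <- 0
  for (i in 1:10) {
    cfg <- sim_config(n = 10, L = 600, theta = 0.01, gc_bias = 2.5)
    tb <- simulate_locus(cfg, 10)
    cl <- classify_sites(tb)
    fc <- fixed_site_composition(cl)
    n_at <- n_at + sum(fc$n_AT); n_gc <- n_gc + sum(fc$n_GC)
  }
  gc_frac <- n_gc / (n_at + n_gc)
  expect_lt(abs(gc_frac - 2.5 / 3.5),
            4 * sqrt(gc_frac * (1 - gc_frac) / (n_at + n_gc)) + 0.02)
  # beta = 1: symmetric composition
  set.seed(32)
  cfg1 <- sim_config(n = 10, L = 2000, theta = 0.01, gc_bias = 1)
  fc1 <- fixed_site_composition(classify_sites(simulate_locus(cfg1, 10)))
  frac1 <- sum(fc1$n_GC) / sum(fc1$n_AT + fc1$n_GC)
  expect_lt(abs(frac1 - 0.5), 0.05)
})
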