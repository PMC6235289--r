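# table with read-weighted haplotypes at chosen sites
hap_table <- function(haps, counts, L = 10, site_i = 2, site_j = 7) {
  seqs <- vapply(haps, function(h) {
    ch <- rep("A", L)
    ch[site_i] <- substr(h, 1, 1)
    ch[site_j] <- substr(h, 2, 2)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  locus_table("hap", seqs, counts)
}

test_that("haplotype counts match hand enumeration with minor labeling", {
  # two alleles only, 50/50: two haplotypes occupied, fully linked
  tb <- hap_table(c("CC", "TT"), c(50, 50))
  p <- pair_haplotype_counts(tb, 2, 7)
  expect_equal(sort(unname(p$counts[p$counts > 0])), c(50, 50))
  expect_true(is_fully_linked(p))
  expect_equal(r_squared(p), 1)
  # four equifrequent haplotypes: D = 0
  tb4 <- hap_table(c("CC", "CT", "TC", "TT"), rep(25, 4))
  p4 <- pair_haplotype_counts(tb4, 2, 7)
  expect_equal(r_squared(p4), 0)
  # 5-allele toy, counts by hand: C major at both sites
  tb5 <- hap_table(c("CC", "CC", "CT", "TC", "TT"), c(30, 10, 20, 25, 15))
  p5 <- pair_haplotype_counts(tb5, 2, 7)
  expect_equal(unname(p5$counts), c(AB = 40, Ab = 20, aB = 25, ab = 15),
               ignore_attr = TRUE)
  expect_equal(p5$f_a, 0.4)   # T at site 2
  expect_equal(p5$f_b, 0.35)  # T at site 7
  expect_equal(p5$x, 5)
  expect_error(pair_haplotype_counts(hap_table(c("CC", "CT"), c(5, 5)), 3, 7),
               "dimorphic")
})

test_that("r-squared follows the arithmetic oracle and the Pearson identity", {
  tb <- hap_table(c("CC", "CT", "TC", "TT"), c(40, 10, 10, 40))
  p <- pair_haplotype_counts(tb, 2, 7)
  expect_equal(r_squared(p), 0.36, tolerance = 1e-12)
  # brute-force equivalence: squared Pearson correlation of site indicators
  # on the read-level matrix
  set.seed(61)
  for (rep in 1:10) {
    counts <- rmultinom(1, 80, c(0.4, 0.2, 0.25, 0.15))[, 1]
    if (min(tapply(counts, c(1, 1, 2, 2), sum)) == 0 ||
        min(tapply(counts, c(1, 2, 1, 2), sum)) == 0) next
    tbr <- hap_table(c("CC", "CT", "TC", "TT"), counts)
    pr <- pair_haplotype_counts(tbr, 2, 7)
    xi <- rep(c(0, 0, 1, 1), counts)
    xj <- rep(c(0, 1, 0, 1), counts)
    expect_equal(r_squared(pr), suppressWarnings(cor(xi, xj))^2,
                 tolerance = 1e-9)
  }
})

test_that("linkage curves bin the stated pair categories", {
  ens <- list(
    pair_haplotype_counts(hap_table(c("CC", "TT"), c(50, 50)), 2, 7),
    pair_haplotype_counts(hap_table(c("CC", "CT", "TC"), c(50, 25, 25)), 2, 7),
    pair_haplotype_counts(hap_table(c("CC", "CT", "TC", "TT"),
                                    c(40, 10, 10, 40)), 2, 7))
  cv <- linkage_curves(ens, bins = c(0, 10))
  expect_equal(cv$n_pairs, 3L)
  expect_equal(cv$fully_linked, 1 / 3)
  expect_equal(cv$ab_absent, 1 / 3)
  # hand values: D = -1/16 for the ab-absent pair, so r2 = 1/9
  expect_equal(cv$mean_r2, mean(c(1, 1 / 9, 0.36)), tolerance = 1e-9)
  # empty bin gives missing values
  cv2 <- linkage_curves(ens, bins = c(0, 2, 10))
  expect_true(is.na(cv2$mean_r2[1]))
  # perfectly linked ensemble: fully-linked fraction 1 everywhere
  ens1 <- ens[1]
  expect_equal(linkage_curves(ens1, c(0, 10))$fully_linked, 1)
})

test_that("recombination decays linkage with separation; asexual stays flat", {
  set.seed(62)
  collect_pairs <- function(rho, n_loci) {
    out <- list()
    for (i in seq_len(n_loci)) {
      tb <- simulate_locus(sim_config(n = 60, L = 400, theta = 0.02,
                                      rho = rho), 60)
      out <- c(out, locus_pair_ensemble(tb, max_pairs = 150))
    }
    out
  }
  sexual <- collect_pairs(0.1, 6)
  cv <- linkage_curves(sexual, bins = c(0, 50, 400))
  expect_gt(cv$inv_mean_r2[2], cv$inv_mean_r2[1])
  asexual <- collect_pairs(0, 6)
  cva <- linkage_curves(asexual, bins = c(0, 50, 400))
  # flat within a factor-2 band (no systematic decay)
  expect_lt(abs(log(cva$mean_r2[2] / cva$mean_r2[1])), log(2.5))
})

test_that("downsampling reproduces the target joint spectrum exactly without
           inheriting the amino-acid linkage", {
  set.seed(63)
  # synonymous pairs: unlinked (independent sites); aa pairs: fully linked
  mk_unlinked <- function() {
    f1 <- runif(1, 0.1, 0.4); f2 <- runif(1, 0.1, 0.4)
    counts <- rmultinom(1, 200, c((1 - f1) * (1 - f2), (1 - f1) * f2,
                                  f1 * (1 - f2), f1 * f2))[, 1]
    if (any(tapply(counts, c(1, 1, 2, 2), sum) == 0) ||
        any(tapply(counts, c(1, 2, 1, 2), sum) == 0)) return(NULL)
    pair_haplotype_counts(hap_table(c("CC", "CT", "TC", "TT"), counts), 2, 7)
  }
  mk_linked <- function() {
    f <- runif(1, 0.1, 0.4)
    counts <- round(200 * c(1 - f, 0, 0, f))
    pair_haplotype_counts(hap_table(c("CC", "TT"), counts[c(1, 4)]), 2, 7)
  }
  syn <- Filter(Negate(is.null), replicate(150, mk_unlinked(),
                                           simplify = FALSE))
  aa <- replicate(40, mk_linked(), simplify = FALSE)
  ds <- suppressWarnings(downsample_matched(syn, aa, n_draws = 5, seed = 64))
  jb <- function(pairs) sort(table(vapply(pairs, micdiv:::joint_freq_bin, "")))
  target <- jb(aa)
  for (d in ds$draws) {
    got <- jb(d)
    kept <- setdiff(names(target), ds$dropped_bins)
    expect_equal(as.integer(got[kept]), as.integer(target[kept]))
  }
  # matched draws keep synonymous (unlinked) conditional structure
  frac_fl <- mean(vapply(ds$draws[[1]], is_fully_linked, TRUE))
  expect_lt(frac_fl, 0.2)
  # aa subset of syn with identical spectrum: histogram matches exactly
  ds2 <- downsample_matched(syn, syn[1:20], n_draws = 2, seed = 65)
  expect_length(ds2$dropped_bins, 0)
})

test_that("main-cloud site exclusion filters by locus and position", {
  p1 <- pair_haplotype_counts(hap_table(c("CC", "TT"), c(5, 5)), 2, 7)
  p2 <- pair_haplotype_counts(hap_table(c("CC", "TT"), c(5, 5)), 2, 7)
  p2$locus_id <- "other"
  mc <- data.frame(locus_id = "hap", position = 2)
  out <- exclude_main_cloud_sites(list(p1, p2), mc)
  expect_length(out, 1)
  expect_equal(out[[1]]$locus_id, "other")
  # disjoint site sets: identity
  mc2 <- data.frame(locus_id = "hap", position = 5)
  expect_length(exclude_main_cloud_sites(list(p1, p2), mc2), 2)
  # everything excluded
  mc3 <- data.frame(locus_id = c("hap", "other"), position = c(2, 2))
  expect_length(exclude_main_cloud_sites(list(p1, p2), mc3), 0)
})
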