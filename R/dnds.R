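# dn/ds statistics: codon-counting (Nei-Gojobori-style with Jukes-Cantor
# correction) and internal error-normalized methods, per-locus and pooled
# summaries, single-coalescence-time divergence fits, and GC-bias
# bookkeeping for genome pairs.

#' Codon-level difference trichotomy of a codon alignment
#'
#' Each non-gapped codon pair is identical, synonymous (same amino acid,
#' different codon), or non-synonymous (different amino acids). Reference
#' codons that are interior stop codons are skipped with a warning.
#'
#' @param codon_alignment a [codon_align] result
#' @return list: n_syn, n_nonsyn, n_codons (pairs compared)
#' @export
count_codon_differences <- function(codon_alignment) {
  rc <- codon_alignment$ref_codons
  ac <- codon_alignment$allele_codons
  ok <- !is.na(rc) & !is.na(ac) & !grepl("[^ACGT]", rc) & !grepl("[^ACGT]", ac)
  rc <- rc[ok]; ac <- ac[ok]
  if (length(rc) > 1) {
    interior_stop <- translate_codon(rc[-length(rc)]) == "*"
    if (any(interior_stop)) {
      warning(sprintf("%d interior stop codon(s) in reference CDS skipped",
                      sum(interior_stop)))
      drop <- c(interior_stop, FALSE)
      rc <- rc[!drop]; ac <- ac[!drop]
    }
  }
  diffc <- rc != ac
  aa_r <- translate_codon(rc[diffc]); aa_a <- translate_codon(ac[diffc])
  list(n_syn = sum(aa_r == aa_a), n_nonsyn = sum(aa_r != aa_a),
       n_codons = length(rc))
}

dnds_result <- function(d_s, d_n, method, n_syn, n_nonsyn, n_codons) {
  ratio <- if (is.na(d_s) || is.na(d_n) || d_s == 0) NA_real_ else d_n / d_s
  structure(list(d_s = d_s, d_n = d_n, ratio = ratio, method = method,
                 n_syn_diffs = n_syn, n_nonsyn_diffs = n_nonsyn,
                 n_codons = n_codons), class = "dnds_result")
}

#' Expected codon-difference counts under pure i.i.d. errors
#'
#' Exact enumeration, per reference codon, of single-base errors weighted by
#' the substitution-rate matrix (per read per site), plus the two-error
#' codon term at second order: the normalizers of the internal dn/ds.
#'
#' @param ref_codons character vector of reference codons (NA / non-ACGT
#'   skipped)
#' @param lambda 4x4 substitution-rate matrix, row = true base
#' @return named vector: E_syn, E_ns
#' @export
expected_error_differences <- function(ref_codons, lambda) {
  E_syn <- E_ns <- 0
  cache <- new.env(parent = emptyenv())
  for (codon in ref_codons) {
    if (is.na(codon) || grepl("[^ACGT]", codon)) next
    hit <- get0(codon, envir = cache)
    if (is.null(hit)) {
      aa0 <- translate_codon(codon)
      chars <- strsplit(codon, "")[[1]]
      e1s <- e1n <- 0
      vars <- single_base_variants(codon)
      w1 <- lambda[cbind(vars$from, vars$to)]
      syn1 <- translate_codon(vars$codon) == aa0
      e1s <- sum(w1[syn1]); e1n <- sum(w1[!syn1])
      # two-error term: all position pairs and target pairs
      e2s <- e2n <- 0
      for (p1 in 1:2) for (p2 in (p1 + 1):3) {
        for (t1 in setdiff(NUCS, chars[p1])) for (t2 in setdiff(NUCS, chars[p2])) {
          mutated <- chars
          mutated[p1] <- t1; mutated[p2] <- t2
          w <- lambda[chars[p1], t1] * lambda[chars[p2], t2]
          if (translate_codon(paste(mutated, collapse = "")) == aa0)
            e2s <- e2s + w else e2n <- e2n + w
        }
      }
      hit <- c(s = e1s + e2s, n = e1n + e2n)
      assign(codon, hit, envir = cache)
    }
    E_syn <- E_syn + hit["s"]
    E_ns <- E_ns + hit["n"]
  }
  c(E_syn = unname(E_syn), E_ns = unname(E_ns))
}

#' Internal (error-normalized) dn/ds
#'
#' Observed synonymous and non-synonymous codon-difference counts are each
#' normalized by their expected number were all differences i.i.d.
#' sequencing/PCR errors with the model's substitution-rate matrix; no
#' multiple-hit correction is applied. On pure-error alignments the mean
#' d_n and d_s are both 1 by construction.
#'
#' @param codon_alignment a [codon_align] result
#' @param error_model an [error_model] (its `lambda_sub` supplies the rates)
#' @param expected_counts optional precomputed result of the expected-count
#'   enumeration for these reference codons (named E_syn/E_ns), so many
#'   reads against one source allele can share it
#' @return a `dnds_result` with method "internal" (missing when an expected
#'   count is zero)
#' @export
dnds_internal <- function(codon_alignment, error_model,
                          expected_counts = NULL) {
  obs <- count_codon_differences(codon_alignment)
  E <- if (!is.null(expected_counts)) expected_counts else
    expected_error_differences(codon_alignment$ref_codons,
                               error_model$lambda_sub)
  d_s <- if (E["E_syn"] > 0) obs$n_syn / E["E_syn"] else NA_real_
  d_n <- if (E["E_ns"] > 0) obs$n_nonsyn / E["E_ns"] else NA_real_
  dnds_result(unname(d_s), unname(d_n), "internal",
              obs$n_syn, obs$n_nonsyn, obs$n_codons)
}

# Nei-Gojobori synonymous site count of one codon (changes to stop count as
# non-synonymous)
ng_syn_sites <- function(codon) {
  cached <- get0(codon, envir = .codon_env$ng_sites)
  if (!is.null(cached)) return(cached)
  aa0 <- translate_codon(codon)
  vars <- single_base_variants(codon)
  out <- sum(translate_codon(vars$codon) == aa0) / 3
  assign(codon, out, envir = .codon_env$ng_sites)
  out
}

# pathway-averaged synonymous / non-synonymous substitution counts between
# two codons (all change orders weighted equally)
ng_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  cached <- get0(key, envir = .codon_env$ng_paths)
  if (!is.null(cached)) return(cached)
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diffpos <- which(ch1 != ch2)
  nd <- length(diffpos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) list(diffpos) else {
    if (nd == 2) list(diffpos, rev(diffpos)) else {
      idx <- list()
      for (a in 1:3) for (b in setdiff(1:3, a))
        idx[[length(idx) + 1]] <- diffpos[c(a, b, setdiff(1:3, c(a, b)))]
      idx
    }
  }
  syn <- nonsyn <- 0
  for (path in perms) {
    cur <- ch1
    for (p in path) {
      nxt <- cur
      nxt[p] <- ch2[p]
      if (translate_codon(paste(cur, collapse = "")) ==
          translate_codon(paste(nxt, collapse = ""))) syn <- syn + 1 else
            nonsyn <- nonsyn + 1
      cur <- nxt
    }
  }
  out <- c(syn = syn / length(perms), nonsyn = nonsyn / length(perms))
  assign(key, out, envir = .codon_env$ng_paths)
  out
}

ng_counts_from_alignment <- function(codon_alignment) {
  rc <- codon_alignment$ref_codons
  ac <- codon_alignment$allele_codons
  ok <- !is.na(rc) & !is.na(ac) & !grepl("[^ACGT]", rc) & !grepl("[^ACGT]", ac)
  rc <- rc[ok]; ac <- ac[ok]
  S <- Sd <- Nd <- 0
  for (k in seq_along(rc)) {
    S <- S + (ng_syn_sites(rc[k]) + ng_syn_sites(ac[k])) / 2
    pc <- ng_path_counts(rc[k], ac[k])
    Sd <- Sd + pc["syn"]; Nd <- Nd + pc["nonsyn"]
  }
  c(S = S, N = 3 * length(rc) - S, Sd = unname(Sd), Nd = unname(Nd),
    n_codons = length(rc))
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Counting-method dn/ds (Nei-Gojobori sites, Jukes-Cantor correction)
#'
#' Synonymous/non-synonymous site counts are averaged over the two
#' sequences, substitution counts are pathway-averaged, and the proportions
#' are multiple-hit corrected; saturated proportions (p >= 3/4) give a
#' missing value.
#'
#' @param codon_alignment a [codon_align] result with >= 1 non-gapped codon
#' @return a `dnds_result` with method "counting"
#' @export
dnds_counting <- function(codon_alignment) {
  cnt <- ng_counts_from_alignment(codon_alignment)
  d_s <- if (cnt["S"] > 0) jc_correct(cnt["Sd"] / cnt["S"]) else NA_real_
  d_n <- if (cnt["N"] > 0) jc_correct(cnt["Nd"] / cnt["N"]) else NA_real_
  obs <- count_codon_differences(codon_alignment)
  dnds_result(unname(d_s), unname(d_n), "counting",
              obs$n_syn, obs$n_nonsyn, cnt[["n_codons"]])
}

#' Frequency-weighted per-locus d_n and d_s
#'
#' Weighted mean of the chosen method's d_n and d_s over ordered allele
#' pairs (weights f_i * f_j, self-pairs contributing zero divergence);
#' pairs with a missing value are dropped from the corresponding mean.
#'
#' @param table a [locus_table] with a designated CDS
#' @param method "counting" or "internal"
#' @param error_model required for the internal method
#' @return list: d_n, d_s (frequency-weighted means)
#' @export
per_locus_weighted_dnds <- function(table, method = c("counting", "internal"),
                                    error_model = NULL) {
  method <- match.arg(method)
  cas <- table_codon_alignments(table)
  f <- table$alleles$frequency
  k <- length(cas)
  wn <- ws <- 0; dn_acc <- ds_acc <- 0
  self_w <- sum(f^2)
  dn_acc <- dn_acc + 0; ds_acc <- ds_acc + 0
  wn <- wn + self_w; ws <- ws + self_w
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      pair_ca <- structure(list(ref_codons = cas[[i]]$allele_codons,
                                allele_codons = cas[[j]]$allele_codons,
                                n_codons = cas[[i]]$n_codons),
                           class = "codon_alignment")
      res <- if (method == "counting") dnds_counting(pair_ca) else
        dnds_internal(pair_ca, error_model)
      w <- 2 * f[i] * f[j]
      if (!is.na(res$d_n)) { dn_acc <- dn_acc + w * res$d_n; wn <- wn + w }
      if (!is.na(res$d_s)) { ds_acc <- ds_acc + w * res$d_s; ws <- ws + w }
    }
  }
  list(d_n = if (wn > 0) dn_acc / wn else NA_real_,
       d_s = if (ws > 0) ds_acc / ws else NA_real_)
}

#' Pooled (concatenated) dn/ds over many alignments
#'
#' Counts are pooled across loci before forming d_n and d_s (counting
#' method), then the ratio taken: the genome-wide MLE-style estimate, not a
#' mean of per-locus ratios.
#'
#' @param alignments list of [codon_align] results
#' @return a `dnds_result`
#' @export
concatenated_mle <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  tot <- c(S = 0, N = 0, Sd = 0, Nd = 0, n_codons = 0)
  n_syn <- n_ns <- 0
  for (ca in alignments) {
    tot <- tot + ng_counts_from_alignment(ca)
    obs <- count_codon_differences(ca)
    n_syn <- n_syn + obs$n_syn; n_ns <- n_ns + obs$n_nonsyn
  }
  d_s <- if (tot["S"] > 0) jc_correct(tot[["Sd"]] / tot[["S"]]) else NA_real_
  d_n <- if (tot["N"] > 0) jc_correct(tot[["Nd"]] / tot[["N"]]) else NA_real_
  dnds_result(d_s, d_n, "counting", n_syn, n_ns, tot[["n_codons"]])
}

#' Binned moving average of d_n against d_s
#'
#' @param points data.frame with columns d_s, d_n
#' @param scheme "window_0.05" (fixed windows of width 0.05 in d_s) or
#'   "equal_count_30" (30 bins with equal numbers of points)
#' @return data.frame: bin_center, mean_dn, n_points
#' @export
binned_dn_vs_ds <- function(points, scheme = c("window_0.05",
                                               "equal_count_30")) {
  scheme <- match.arg(scheme)
  pts <- points[!is.na(points$d_s) & !is.na(points$d_n), , drop = FALSE]
  if (scheme == "window_0.05") {
    b <- floor(pts$d_s / 0.05)
    out <- lapply(sort(unique(b)), function(k)
      data.frame(bin_center = 0.05 * k + 0.025,
                 mean_dn = mean(pts$d_n[b == k]), n_points = sum(b == k)))
  } else {
    ord <- order(pts$d_s)
    grp <- ceiling(seq_along(ord) / (length(ord) / 30))
    out <- lapply(sort(unique(grp)), function(g) {
      sel <- ord[grp == g]
      data.frame(bin_center = mean(pts$d_s[sel]),
                 mean_dn = mean(pts$d_n[sel]), n_points = length(sel))
    })
  }
  do.call(rbind, out)
}

#' Least-squares fit of d_n on d_s
#'
#' @param points data.frame with columns d_s, d_n
#' @param through_origin force a zero intercept
#' @return list: slope, intercept (0 for through-origin), ci (95% CI on the
#'   slope), r_squared
#' @export
fit_dn_ds <- function(points, through_origin = TRUE) {
  pts <- points[!is.na(points$d_s) & !is.na(points$d_n), , drop = FALSE]
  stopifnot(nrow(pts) >= 2)
  if (!through_origin && stats::sd(pts$d_s) == 0)
    stop("degenerate fit: all d_s equal")
  fit <- if (through_origin) stats::lm(d_n ~ 0 + d_s, data = pts) else
    stats::lm(d_n ~ d_s, data = pts)
  sm <- summary(fit)
  co <- sm$coefficients
  srow <- which(rownames(co) == "d_s")
  slope <- co[srow, 1]; se <- co[srow, 2]
  list(slope = unname(slope),
       intercept = if (through_origin) 0 else unname(co[1, 1]),
       ci = unname(slope + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se),
       r_squared = sm$r.squared)
}

#' Single-coalescence-time fit of per-locus mutated-unit counts
#'
#' All loci are assumed to share one divergence time, so each unit
#' (four-fold-degenerate codon for theta_s, amino-acid site for theta_n)
#' has mutated independently with a common probability; the closed-form MLE
#' is the pooled fraction sum(counts)/sum(sites). The expected count
#' histogram is the exact sites-weighted mixture of binomials.
#'
#' @param counts per-locus mutated-unit counts
#' @param sites per-locus unit totals (counts_i <= sites_i)
#' @return object of class `poisson_divergence_fit`: theta_hat, counts,
#'   sites, expected (data.frame k, expected number of loci)
#' @export
poisson_single_time_fit <- function(counts, sites) {
  stopifnot(length(counts) == length(sites), all(counts <= sites),
            all(counts >= 0))
  if (sum(sites) == 0) stop("no units: sum(sites) = 0")
  theta_hat <- sum(counts) / sum(sites)
  kmax <- max(sites)
  expected <- rep(0, kmax + 1)
  for (m in unique(sites)) {
    nm <- sum(sites == m)
    expected[1:(m + 1)] <- expected[1:(m + 1)] +
      nm * stats::dbinom(0:m, m, theta_hat)
  }
  structure(list(theta_hat = theta_hat, counts = counts, sites = sites,
                 expected = data.frame(k = 0:kmax, expected = expected)),
            class = "poisson_divergence_fit")
}

#' Split loci into low/high divergence groups by d_s
#'
#' @param per_locus_ds per-locus d_s values
#' @param threshold boundary (d_s >= threshold is "high")
#' @return list: labels ("low"/"high"), n_low, n_high
#' @export
split_divergence_groups <- function(per_locus_ds, threshold = 0.3) {
  labels <- ifelse(per_locus_ds >= threshold, "high", "low")
  list(labels = labels, n_low = sum(labels == "low"),
       n_high = sum(labels == "high"))
}

#' GC-bias bookkeeping over synonymous site pairs of two genomes
#'
#' Classifies every synonymous site pair into: conserved; A<->T / C<->G
#' transversions (GC content unchanged; the C<->G count is reported);
#' transitions (polarized: GC in the first genome); and A<->C / G<->T
#' transversions (polarized likewise). The GC:AT odds of each genome follow
#' from the polarized counts.
#'
#' @param bases_first,bases_second equal-length character vectors of the
#'   two genomes' bases at synonymous sites (gaps and non-ACGT skipped and
#'   tallied)
#' @return list of class `gc_bias_counts`: class counts, polarized GC
#'   counts, per-genome GC totals and biases
#' @export
gc_bias_bookkeeping <- function(bases_first, bases_second) {
  stopifnot(length(bases_first) == length(bases_second))
  ok <- bases_first %in% NUCS & bases_second %in% NUCS
  n_skipped <- sum(!ok)
  b1 <- bases_first[ok]; b2 <- bases_second[ok]
  gc1 <- b1 %in% c("G", "C"); gc2 <- b2 %in% c("G", "C")
  conserved <- b1 == b2
  transition <- !conserved & unname(TRANSITION_PARTNER[b1]) == b2
  tv <- !conserved & !transition
  tv_ACTG <- tv & (gc1 == gc2)        # A<->T or C<->G: GC content unchanged
  tv_AGCT <- tv & (gc1 != gc2)        # A<->C or G<->T
  n_total <- length(b1)
  counts <- list(
    n_total = n_total,
    n_conserved = sum(conserved), conserved_gc = sum(conserved & gc1),
    n_tv_ACTG = sum(tv_ACTG), tv_ACTG_cg = sum(tv_ACTG & gc1),
    n_transitions = sum(transition), transitions_gc_first = sum(transition & gc1),
    n_tv_AGCT = sum(tv_AGCT), tv_AGCT_gc_first = sum(tv_AGCT & gc1),
    n_skipped = n_skipped)
  counts$gc_first <- sum(gc1)
  counts$gc_second <- sum(gc2)
  counts$bias_first <- counts$gc_first / (n_total - counts$gc_first)
  counts$bias_second <- counts$gc_second / (n_total - counts$gc_second)
  counts$transition_gc_first_fraction <-
    if (counts$n_transitions > 0)
      counts$transitions_gc_first / counts$n_transitions else NA_real_
  structure(counts, class = "gc_bias_counts")
}
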