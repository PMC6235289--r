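# Rank-frequency spectra with null bands, per-locus heterozygosity and its
# null distribution, and coalescent-time arithmetic.

QUINTILES <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

rank_quantile_matrix <- function(freq_lists, max_rank, probs = QUINTILES) {
  boundaries <- matrix(NA_real_, length(probs), max_rank,
                       dimnames = list(paste0("q", probs * 100), NULL))
  for (r in seq_len(max_rank)) {
    vals <- unlist(lapply(freq_lists, function(f)
      if (length(f) >= r) f[r] else NULL))
    if (length(vals) > 0)
      boundaries[, r] <- stats::quantile(vals, probs, type = 7)
  }
  boundaries
}

NULL_PROBS <- c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1)   # quintiles plus the median

#' Observed allele rank-frequency quintile bands
#'
#' Frequencies are rank-ordered within each locus; at each rank the
#' 0/20/40/60/80/100 percentiles across loci (linear interpolation) form the
#' band boundaries. Loci lacking a given rank are omitted at that rank.
#'
#' @param tables list of [locus_table]
#' @param min_reads depth screen (the deepest-loci convention is >= 1000)
#' @param max_rank deepest rank reported
#' @return object of class `rank_frequency_bands`: list(ranks, boundaries
#'   matrix with one row per percentile, n_loci, source)
#' @export
rank_frequency_bands <- function(tables, min_reads = 1000, max_rank = 50) {
  keep <- Filter(function(tb) tb$depth >= min_reads, tables)
  stopifnot(length(keep) > 0)
  freq_lists <- lapply(keep, function(tb) tb$alleles$frequency)
  structure(list(ranks = seq_len(max_rank),
                 boundaries = rank_quantile_matrix(freq_lists, max_rank),
                 n_loci = length(keep), source = "observed"),
            class = "rank_frequency_bands")
}

#' Null rank-frequency bands (asexual gamma procedure or recombinant coalescent)
#'
#' Asexual: per replicate, one gamma frequency sample per locus
#' ([sample_asexual_frequencies] with K variables of shape thetaL/K);
#' quintile boundaries are computed across loci within each replicate and
#' averaged over replicates. Recombinant: coalescent loci simulated at the
#' supplied depths; the per-rank median across all simulated loci is
#' reported.
#'
#' @param kind "asexual" or "recombinant"
#' @param theta per-site scaled mutation rate
#' @param L locus length
#' @param depths read depths of the loci being mimicked (length = number of
#'   loci; recombinant simulations use them as leaf counts)
#' @param rho recombination rate (recombinant kind)
#' @param n_reps replicates (asexual averaging; recombinant pools loci from
#'   all replicates)
#' @param K gamma-procedure resolution
#' @param max_rank deepest rank reported
#' @param seed optional integer seed
#' @return `rank_frequency_bands` (recombinant: the `q50` row is the
#'   per-rank median; other rows are percentiles of the pooled loci)
#' @export
null_rank_bands <- function(kind = c("asexual", "recombinant"), theta, L,
                            depths, rho = 0, n_reps = 1000, K = 5000,
                            max_rank = 50, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n_loci <- length(depths)
  if (kind == "asexual") {
    acc <- matrix(0, length(NULL_PROBS), max_rank)
    cnt <- matrix(0, length(NULL_PROBS), max_rank)
    for (rep in seq_len(n_reps)) {
      fl <- lapply(seq_len(n_loci), function(i)
        sample_asexual_frequencies(theta * L, K))
      bb <- rank_quantile_matrix(fl, max_rank, probs = NULL_PROBS)
      ok <- !is.na(bb)
      acc[ok] <- acc[ok] + bb[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    boundaries <- acc / cnt
    boundaries[cnt == 0] <- NA_real_
    rownames(boundaries) <- paste0("q", NULL_PROBS * 100)
  } else {
    fl <- list()
    for (rep in seq_len(n_reps)) {
      for (dep in depths) {
        cfg <- sim_config(n = dep, L = L, theta = theta, rho = rho)
        tb <- simulate_locus(cfg, depth = dep)
        fl[[length(fl) + 1]] <- tb$alleles$frequency
      }
    }
    boundaries <- rank_quantile_matrix(fl, max_rank, probs = NULL_PROBS)
  }
  structure(list(ranks = seq_len(max_rank), boundaries = boundaries,
                 n_loci = n_loci, source = paste0(kind, "_null")),
            class = "rank_frequency_bands")
}

#' Per-locus heterozygosity (overall and by site class)
#'
#' Overall pi: frequency-weighted mean fractional nucleotide distance over
#' ordered allele pairs (self-pairs included, no sample-size correction;
#' each pair's denominator is its alignable column count). With a
#' [classify_sites] result, per-class pi is the mean over classified columns
#' of the single-site heterozygosity 1 - sum_b (n_b/R)^2. pi_aa is the
#' frequency-weighted mean amino-acid distance per non-gapped codon when a
#' designated CDS is present.
#'
#' @param table a [locus_table]
#' @param classification optional result of [classify_sites]
#' @return list of class `heterozygosity_result`: pi, pi_S, pi_aa,
#'   pi_intergenic (NA when not computable)
#' @export
heterozygosity <- function(table, classification = NULL) {
  f <- table$alleles$frequency
  seqs <- table$alleles$sequence
  k <- length(seqs)
  pi <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    pi <- pi + f[i] * f[j] * fractional_divergence(seqs[i], seqs[j])
  }
  pi_aa <- NA_real_
  if (!is.na(table$designated_cds)) {
    cas <- table_codon_alignments(table)
    pi_aa <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      ok <- sum(!is.na(cas[[i]]$allele_codons) &
                  !is.na(cas[[j]]$allele_codons))
      if (ok == 0) next
      pi_aa <- pi_aa + f[i] * f[j] *
        pairwise_distance(cas[[i]], cas[[j]], "amino_acid") / ok
    }
  }
  pi_S <- pi_intergenic <- NA_real_
  if (!is.null(classification)) {
    site_h <- function(classes) {
      sel <- classification$class %in% classes & classification$R > 0
      if (!any(sel)) return(NA_real_)
      counts <- classification[sel, c("A", "C", "G", "T"), drop = FALSE]
      R <- classification$R[sel]
      mean(1 - rowSums((as.matrix(counts) / R)^2))
    }
    pi_S <- site_h(c("syn_third", "syn_first_LRS"))
    pi_intergenic <- site_h("intergenic")
  }
  structure(list(pi = pi, pi_S = pi_S, pi_aa = pi_aa,
                 pi_intergenic = pi_intergenic),
            class = "heterozygosity_result")
}

#' Null distribution of per-locus heterozygosity under neutral coalescence
#'
#' @param theta per-site scaled mutation rate
#' @param L locus length
#' @param depths leaf counts, recycled across replicates
#' @param n_reps number of simulated loci
#' @param rho recombination rate (0 = asexual)
#' @param seed optional integer seed
#' @return list: `pi` (per-locus values), `quantiles`
#' @export
heterozygosity_null <- function(theta, L, depths, n_reps = 100, rho = 0,
                                seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  depths <- rep_len(depths, n_reps)
  pis <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(n = depths[i], L = L, theta = theta, rho = rho)
    tb <- simulate_locus(cfg, depth = depths[i])
    heterozygosity(tb)$pi
  }, 0)
  list(pi = pis,
       quantiles = stats::quantile(pis, c(0.025, 0.25, 0.5, 0.75, 0.975)))
}

#' Coalescent-time estimate from synonymous heterozygosity
#'
#' T_c (generations) = pi_S / (2 mu); years use the supplied generation time.
#'
#' @param pi_S synonymous heterozygosity per site
#' @param mu per-site per-generation mutation rate
#' @param tau_g_days generation time in days
#' @return list of class `coal_time_estimate`: mu, tau_g, T_c_generations,
#'   T_c_years
#' @export
coalescent_time <- function(pi_S, mu, tau_g_days) {
  stopifnot(pi_S >= 0, mu > 0, tau_g_days > 0)
  gens <- pi_S / (2 * mu)
  structure(list(mu = mu, tau_g = tau_g_days, T_c_generations = gens,
                 T_c_years = gens * tau_g_days / 365.25),
            class = "coal_time_estimate")
}
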