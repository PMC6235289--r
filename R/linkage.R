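# Two-site haplotype statistics, distance-dependent linkage curves, and
# joint-frequency-matched downsampling.

#' Haplotype counts for a pair of dimorphic sites
#'
#' Accumulates read-weighted counts of the four haplotypes AB, Ab, aB, ab
#' over alleles with a base at both sites. A and B are the major variants
#' (a, b minor; read-count majority, ties broken by alphabetical order), so
#' ab is the doubly-minor haplotype.
#'
#' @param table a [locus_table]
#' @param site_i,site_j 1-based site positions (site_i < site_j not
#'   required; separation is |site_j - site_i|)
#' @return object of class `pair_haplotype_counts`: counts, frequencies,
#'   minor marginals f_a, f_b, separation x, locus id
#' @export
pair_haplotype_counts <- function(table, site_i, site_j) {
  sm <- seq_matrix(table$alleles$sequence)
  reads <- table$alleles$read_count
  bi <- sm[, site_i]; bj <- sm[, site_j]
  ok <- bi %in% NUCS & bj %in% NUCS
  variants <- function(b) {
    tab <- tapply(reads[ok], b[ok], sum)
    tab <- tab[order(-tab, names(tab))]
    if (length(tab) != 2)
      stop(sprintf("site not dimorphic: %d variant(s) observed", length(tab)))
    names(tab)   # major, minor
  }
  vi <- variants(bi); vj <- variants(bj)
  n <- c(AB = sum(reads[ok & bi == vi[1] & bj == vj[1]]),
         Ab = sum(reads[ok & bi == vi[1] & bj == vj[2]]),
         aB = sum(reads[ok & bi == vi[2] & bj == vj[1]]),
         ab = sum(reads[ok & bi == vi[2] & bj == vj[2]]))
  f <- n / sum(n)
  structure(list(counts = n, freqs = f,
                 f_a = unname(f["aB"] + f["ab"]),
                 f_b = unname(f["Ab"] + f["ab"]),
                 x = abs(site_j - site_i),
                 site_i = site_i, site_j = site_j,
                 locus_id = table$locus_id),
            class = "pair_haplotype_counts")
}

#' Linkage disequilibrium r-squared of a site pair
#'
#' r2 = D^2 / (f_A f_a f_B f_b) with D = f_ab - f_a f_b; pairs where either
#' site is fixed take r2 = 0 by convention.
#'
#' @param counts a [pair_haplotype_counts] (or list with `freqs`, `f_a`,
#'   `f_b`)
#' @return value in [0, 1]
#' @export
r_squared <- function(counts) {
  f_a <- counts$f_a; f_b <- counts$f_b
  if (f_a <= 0 || f_a >= 1 || f_b <= 0 || f_b >= 1) return(0)
  D <- unname(counts$freqs["ab"]) - f_a * f_b
  D^2 / (f_a * (1 - f_a) * f_b * (1 - f_b))
}

is_fully_linked <- function(p) {
  n <- p$counts
  n["Ab"] == 0 && n["aB"] == 0 && n["AB"] > 0 && n["ab"] > 0
}

is_ab_absent <- function(p) {
  n <- p$counts
  n["ab"] == 0 && all(n[c("AB", "Ab", "aB")] > 0)
}

#' Distance-binned linkage curves over an ensemble of site pairs
#'
#' Per separation bin: mean r2 and its reciprocal, the fraction of fully
#' linked pairs (only AB and ab observed), and the fraction with exactly
#' the ab haplotype absent.
#'
#' @param ensemble list of [pair_haplotype_counts]
#' @param bins numeric break points over separation x (right-open bins)
#' @return data.frame: bin_low, bin_high, mean_r2, inv_mean_r2,
#'   fully_linked, ab_absent, n_pairs (empty bins give NA)
#' @export
linkage_curves <- function(ensemble, bins) {
  x <- vapply(ensemble, `[[`, 0, "x")
  r2 <- vapply(ensemble, r_squared, 0)
  fl <- vapply(ensemble, is_fully_linked, TRUE)
  ab0 <- vapply(ensemble, is_ab_absent, TRUE)
  out <- list()
  for (k in seq_len(length(bins) - 1)) {
    sel <- x >= bins[k] & x < bins[k + 1]
    n <- sum(sel)
    out[[k]] <- data.frame(
      bin_low = bins[k], bin_high = bins[k + 1],
      mean_r2 = if (n > 0) mean(r2[sel]) else NA_real_,
      inv_mean_r2 = if (n > 0 && mean(r2[sel]) > 0) 1 / mean(r2[sel]) else NA_real_,
      fully_linked = if (n > 0) mean(fl[sel]) else NA_real_,
      ab_absent = if (n > 0) mean(ab0[sel]) else NA_real_,
      n_pairs = n)
  }
  do.call(rbind, out)
}

# joint minor-frequency bin of a pair: unordered decade-third bins
joint_freq_bin <- function(p) {
  b <- sort(floor(3 * log10(c(p$f_a, p$f_b))))
  paste(b, collapse = ",")
}

#' Downsample synonymous pairs to match an amino-acid joint frequency spectrum
#'
#' Each draw resamples, with replacement, synonymous site pairs so that the
#' binned joint minor-frequency histogram P(f_a, f_b) (logarithmic bins,
#' decade thirds, unordered) equals that of the amino-acid pairs exactly,
#' leaving the conditional haplotype structure of the synonymous pairs
#' untouched. Amino-acid-occupied bins with no synonymous candidates are
#' dropped with a warning.
#'
#' @param syn_pairs,aa_pairs lists of [pair_haplotype_counts]
#' @param n_draws number of downsampled ensembles
#' @param seed optional integer seed
#' @return list of class `pair_ensemble_draws`: `draws` (each a list of
#'   pair_haplotype_counts), `dropped_bins`, `target` histogram
#' @export
downsample_matched <- function(syn_pairs, aa_pairs, n_draws = 1000,
                               seed = NULL) {
  stopifnot(length(syn_pairs) > 0, length(aa_pairs) > 0)
  if (!is.null(seed)) set.seed(seed)
  syn_bins <- vapply(syn_pairs, joint_freq_bin, "")
  aa_bins <- vapply(aa_pairs, joint_freq_bin, "")
  target <- table(aa_bins)
  dropped <- character(0)
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    idx <- integer(0)
    for (b in names(target)) {
      cand <- which(syn_bins == b)
      if (length(cand) == 0) {
        if (d == 1) dropped <- c(dropped, b)
        next
      }
      idx <- c(idx, cand[sample.int(length(cand), target[[b]],
                                    replace = TRUE)])
    }
    draws[[d]] <- syn_pairs[idx]
  }
  if (length(dropped) > 0)
    warning(sprintf("%d joint-frequency bin(s) had no synonymous candidates",
                    length(dropped)))
  structure(list(draws = draws, dropped_bins = dropped,
                 target = as.data.frame(target, stringsAsFactors = FALSE)),
            class = "pair_ensemble_draws")
}

#' Exclude pairs touching main-cloud-polymorphic sites
#'
#' @param full_pairs list of [pair_haplotype_counts]
#' @param main_cloud_polymorphic_sites data.frame(locus_id, position) of
#'   sites polymorphic within the main cloud
#' @return filtered list (provenance attribute "full_minus_main_cloud")
#' @export
exclude_main_cloud_sites <- function(full_pairs,
                                     main_cloud_polymorphic_sites) {
  keys <- paste(main_cloud_polymorphic_sites$locus_id,
                main_cloud_polymorphic_sites$position)
  out <- Filter(function(p)
    !(paste(p$locus_id, p$site_i) %in% keys) &&
      !(paste(p$locus_id, p$site_j) %in% keys), full_pairs)
  attr(out, "provenance") <- "full_minus_main_cloud"
  out
}

#' All dimorphic-site pairs of a locus as haplotype counts
#'
#' Convenience wrapper enumerating sites with exactly two nucleotide
#' variants among the reads and building [pair_haplotype_counts] for every
#' within-locus pair.
#'
#' @param table a [locus_table]
#' @param max_pairs optional cap (pairs are taken in position order)
#' @return list of `pair_haplotype_counts`
#' @export
locus_pair_ensemble <- function(table, max_pairs = Inf) {
  sm <- seq_matrix(table$alleles$sequence)
  reads <- table$alleles$read_count
  dimorphic <- which(vapply(seq_len(ncol(sm)), function(col) {
    b <- sm[, col]
    ok <- b %in% NUCS
    length(unique(b[ok])) == 2
  }, TRUE))
  out <- list()
  if (length(dimorphic) >= 2) {
    for (i in seq_len(length(dimorphic) - 1)) {
      for (j in (i + 1):length(dimorphic)) {
        out[[length(out) + 1]] <-
          pair_haplotype_counts(table, dimorphic[i], dimorphic[j])
        if (length(out) >= max_pairs) return(out)
      }
    }
  }
  out
}
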