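# Frequency-weighted distance spectra, geometric nulls, main-cloud
# partitioning, triangle classification, OTU clustering, and cross-sample
# nearest-allele statistics.

#' Pairwise distance between two aligned sequences or codon alignments
#'
#' Nucleotide: Hamming count. With `indels_included = FALSE` (the default)
#' columns where either sequence has a gap are skipped; including indels
#' additionally counts base-vs-gap columns as differences. Amino-acid:
#' number of codon pairs coding for different amino acids; synonymous:
#' codon pairs coding for the same amino acid via different codons. The
#' aa/synonymous metrics take two [codon_align] results (gapped codons are
#' skipped).
#'
#' @param a,b equal-length sequences (nucleotide metric) or
#'   `codon_alignment` objects (amino_acid / synonymous metrics)
#' @param metric one of "nucleotide", "amino_acid", "synonymous"
#' @param indels_included nucleotide metric only
#' @return non-negative integer distance
#' @export
pairwise_distance <- function(a, b, metric = c("nucleotide", "amino_acid",
                                               "synonymous"),
                              indels_included = FALSE) {
  metric <- match.arg(metric)
  if (metric == "nucleotide") {
    am <- strsplit(a, "")[[1]]; bm <- strsplit(b, "")[[1]]
    stopifnot(length(am) == length(bm))
    gap <- am == "-" | bm == "-"
    d <- sum(am[!gap] != bm[!gap])
    if (indels_included) d <- d + sum(xor(am == "-", bm == "-"))
    return(as.integer(d))
  }
  if (!inherits(a, "codon_alignment") || !inherits(b, "codon_alignment"))
    stop("amino_acid/synonymous metrics require codon alignments ",
         "(a designated CDS)")
  ca <- a$allele_codons; cb <- b$allele_codons
  stopifnot(length(ca) == length(cb))
  ok <- !is.na(ca) & !is.na(cb)
  ca <- ca[ok]; cb <- cb[ok]
  diffc <- ca != cb
  aa_a <- translate_codon(ca[diffc]); aa_b <- translate_codon(cb[diffc])
  if (metric == "amino_acid") return(as.integer(sum(aa_a != aa_b)))
  as.integer(sum(aa_a == aa_b))
}

# codon alignments for every allele of a table (list indexed by allele row)
table_codon_alignments <- function(table) {
  lapply(seq_len(nrow(table$alleles)), codon_align, table = table)
}

locus_distance_objects <- function(table, metric) {
  if (metric == "nucleotide") table$alleles$sequence else
    table_codon_alignments(table)
}

#' Frequency-weighted distance spectrum over loci
#'
#' Per locus, distances between ordered allele pairs (i, j) are weighted
#' f_i * f_j (all-pairs mode, self-pairs included by default so identical
#' draws contribute mass at zero), or f_i for distances away from the most
#' abundant allele or from a reference homolog. Per-locus spectra are
#' normalized and then averaged across loci with equal weight.
#'
#' @param tables list of [locus_table]
#' @param metric distance metric, see [pairwise_distance]
#' @param mode "all_pairs", "from_most_abundant", or "from_reference"
#' @param indels_included nucleotide metric only
#' @param include_self include self-pairs (weight f_i^2) in all-pairs mode
#' @param reference which reference slot to use in from_reference mode
#' @return object of class `distance_spectrum`: data.frame(distance, mass)
#' @export
weighted_distance_spectrum <- function(tables,
                                       metric = "nucleotide",
                                       mode = c("all_pairs",
                                                "from_most_abundant",
                                                "from_reference"),
                                       indels_included = FALSE,
                                       include_self = TRUE,
                                       reference = c("ref_b", "ref_a")) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  stopifnot(length(tables) >= 1)
  per_locus <- list()
  for (tb in tables) {
    objs <- locus_distance_objects(tb, metric)
    f <- tb$alleles$frequency
    k <- length(objs)
    d <- numeric(0); w <- numeric(0)
    if (mode == "all_pairs") {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (!include_self && i == j) next
        d <- c(d, if (i == j) 0 else
          pairwise_distance(objs[[i]], objs[[j]], metric, indels_included))
        w <- c(w, f[i] * f[j])
      }
    } else if (mode == "from_most_abundant") {
      for (i in seq_len(k)) {
        d <- c(d, pairwise_distance(objs[[i]], objs[[1]], metric,
                                    indels_included))
        w <- c(w, f[i])
      }
    } else {
      refseq <- if (reference == "ref_b") tb$ref_b else tb$ref_a
      if (is.null(refseq)) stop(sprintf("locus %s: no %s", tb$locus_id, reference))
      refobj <- if (metric == "nucleotide") refseq else codon_align(refseq, tb)
      for (i in seq_len(k)) {
        d <- c(d, pairwise_distance(objs[[i]], refobj, metric, indels_included))
        w <- c(w, f[i])
      }
    }
    agg <- tapply(w, d, sum)
    per_locus[[length(per_locus) + 1]] <-
      data.frame(distance = as.integer(names(agg)),
                 mass = as.numeric(agg) / sum(agg))
  }
  all_d <- sort(unique(unlist(lapply(per_locus, `[[`, "distance"))))
  mass <- rep(0, length(all_d))
  for (pl in per_locus)
    mass[match(pl$distance, all_d)] <- mass[match(pl$distance, all_d)] +
      pl$mass / length(per_locus)
  structure(data.frame(distance = all_d, mass = mass),
            class = c("distance_spectrum", "data.frame"),
            metric = metric, mode = mode, indels_included = indels_included)
}

#' Mean of a distance spectrum
#' @param spectrum a `distance_spectrum`
#' @return weighted mean distance
#' @export
spectrum_mean <- function(spectrum) sum(spectrum$distance * spectrum$mass)

#' Geometric distance spectrum (asexual neutral-drift null)
#'
#' P(d) = (1/(1+m)) * (m/(1+m))^d, the distribution of pairwise distances
#' when the pair coalescence rate is time-independent and the mean distance
#' is m.
#'
#' @param mean m > 0 (use a small value for the degenerate all-mass-at-zero
#'   limit)
#' @param tol truncation tolerance for the support
#' @return `distance_spectrum` over 0..d_max with cumulative mass
#'   >= 1 - tol (renormalized)
#' @export
geometric_null <- function(mean, tol = 1e-9) {
  stopifnot(mean > 0)
  p <- 1 / (1 + mean)
  d_max <- max(0, ceiling(log(tol) / log(1 - p)))
  d <- 0:d_max
  mass <- p * (1 - p)^d
  structure(data.frame(distance = d, mass = mass / sum(mass)),
            class = c("distance_spectrum", "data.frame"),
            metric = "nucleotide", mode = "null")
}

#' Partition a locus into main-cloud and outlier alleles
#'
#' Main cloud: alleles whose nucleotide divergence (indels excluded, over
#' the pair's alignable columns) from the most abundant allele is <= the
#' threshold (boundary inclusive).
#'
#' @param table a [locus_table]
#' @param threshold fractional divergence cut
#' @return list with `labels` ("main_cloud"/"outlier" per allele),
#'   `divergence`, `frac_alleles`, `frac_reads`
#' @export
main_cloud_partition <- function(table, threshold = 0.10) {
  seqs <- table$alleles$sequence
  top <- seqs[1]
  div <- vapply(seqs, function(s) {
    d <- pairwise_distance(s, top, "nucleotide", indels_included = FALSE)
    am <- strsplit(s, "")[[1]]; bm <- strsplit(top, "")[[1]]
    len <- sum(am != "-" & bm != "-")
    if (len == 0) 1 else d / len
  }, 0, USE.NAMES = FALSE)
  labels <- ifelse(div <= threshold, "main_cloud", "outlier")
  list(labels = labels, divergence = div,
       frac_alleles = mean(labels == "main_cloud"),
       frac_reads = sum(table$alleles$frequency[labels == "main_cloud"]))
}

fractional_divergence <- function(a, b) {
  d <- pairwise_distance(a, b, "nucleotide", indels_included = FALSE)
  am <- strsplit(a, "")[[1]]; bm <- strsplit(b, "")[[1]]
  len <- sum(am != "-" & bm != "-")
  if (len == 0) 1 else d / len
}

#' Classify the reference/most-abundant-allele triangle of a locus
#'
#' Edge lengths are fractional divergences among the most abundant allele
#' (M) and the two reference homologs. Type A: ref_b inside the main cloud
#' (d_MB <= cloud threshold) and ref_a outside; Type B: both inside; Type C:
#' both outside, references > cloud threshold apart, and at least one allele
#' within `near_threshold` of each reference; otherwise "other". Precedence
#' A, B, C.
#'
#' @param table a [locus_table] with both references
#' @param cloud_threshold main-cloud radius
#' @param near_threshold "read found nearby" radius for Type C
#' @return list of class `triangle_record`: d_MB, d_MA, d_AB, type
#' @export
classify_triangle <- function(table, cloud_threshold = 0.10,
                              near_threshold = 0.03) {
  if (is.null(table$ref_b) || is.null(table$ref_a))
    stop(sprintf("locus %s: triangle needs both references", table$locus_id))
  top <- table$alleles$sequence[1]
  d_MB <- fractional_divergence(top, table$ref_b)
  d_MA <- fractional_divergence(top, table$ref_a)
  d_AB <- fractional_divergence(table$ref_a, table$ref_b)
  type <- "other"
  if (d_MB <= cloud_threshold && d_MA > cloud_threshold) {
    type <- "A"
  } else if (d_MB <= cloud_threshold && d_MA <= cloud_threshold) {
    type <- "B"
  } else if (d_MB > cloud_threshold && d_MA > cloud_threshold &&
             d_AB > cloud_threshold) {
    near_b <- any(vapply(table$alleles$sequence, fractional_divergence, 0,
                         b = table$ref_b) < near_threshold)
    near_a <- any(vapply(table$alleles$sequence, fractional_divergence, 0,
                         b = table$ref_a) < near_threshold)
    if (near_a && near_b) type <- "C"
  }
  structure(list(d_MB = d_MB, d_MA = d_MA, d_AB = d_AB, type = type),
            class = "triangle_record")
}

#' Complete-linkage OTU clustering at a fractional distance threshold
#'
#' @param alleles character vector of aligned sequences
#' @param threshold cluster diameter cut (e.g. 0.03 or 0.06)
#' @return integer cluster assignment (1-based, in order of first appearance)
#' @export
cluster_otus <- function(alleles, threshold = 0.03) {
  k <- length(alleles)
  if (k == 1) return(1L)
  dm <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    dm[i, j] <- dm[j, i] <- fractional_divergence(alleles[i], alleles[j])
  if (all(dm == 0)) return(rep(1L, k))
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  cl <- stats::cutree(hc, h = threshold)
  as.integer(match(cl, unique(cl)))
}

half_log_bin <- function(f) floor(2 * log10(f))

#' Nearest-allele statistics for external reads against deep allele tables
#'
#' @param reads data.frame with columns `sequence` and `locus_id`
#' @param tables named list of [locus_table] (names = locus ids)
#' @param raw_reads optional data.frame(sequence, locus_id) of raw reads;
#'   a read matching a raw read exactly (but no allele) is assigned the
#'   frequency of the allele closest to that raw read
#' @param n_null number of frequency-weighted resampling draws for the null
#'   matched-frequency spectrum
#' @param seed optional seed for the resampling null
#' @return list: `distances` (per-read nearest distance, NA when the locus
#'   is unknown), `matched_freq` (frequencies of exactly matched alleles),
#'   `matched_spectrum` / `null_spectrum` (half-log-bin tables),
#'   `n_skipped` reads with unknown locus
#' @export
nearest_allele_stats <- function(reads, tables, raw_reads = NULL,
                                 n_null = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("sequence", "locus_id") %in% names(reads)))
  dist_out <- rep(NA_integer_, nrow(reads))
  matched_freq <- numeric(0)
  n_skipped <- 0
  for (r in seq_len(nrow(reads))) {
    tb <- tables[[reads$locus_id[r]]]
    if (is.null(tb)) { n_skipped <- n_skipped + 1; next }
    dd <- vapply(tb$alleles$sequence, pairwise_distance, 0L,
                 b = reads$sequence[r], metric = "nucleotide",
                 USE.NAMES = FALSE)
    dist_out[r] <- min(dd)
    if (min(dd) == 0) {
      matched_freq <- c(matched_freq, tb$alleles$frequency[which.min(dd)])
    } else if (!is.null(raw_reads)) {
      rr <- raw_reads[raw_reads$locus_id == reads$locus_id[r], , drop = FALSE]
      if (nrow(rr) > 0 && reads$sequence[r] %in% rr$sequence) {
        dist_out[r] <- 0L
        matched_freq <- c(matched_freq, tb$alleles$frequency[which.min(dd)])
      }
    }
  }
  # frequency-weighted resampling null over the loci actually queried
  known <- reads$locus_id[reads$locus_id %in% names(tables)]
  null_freq <- numeric(0)
  if (length(known) > 0 && n_null > 0) {
    loci <- sample(known, n_null, replace = TRUE)
    null_freq <- vapply(loci, function(loc) {
      tb <- tables[[loc]]
      sample(tb$alleles$frequency, 1, prob = tb$alleles$frequency)
    }, 0, USE.NAMES = FALSE)
  }
  bin_table <- function(f) {
    if (length(f) == 0)
      return(data.frame(bin = integer(0), fraction = numeric(0)))
    b <- half_log_bin(f)
    tb <- table(b)
    data.frame(bin = as.integer(names(tb)),
               fraction = as.numeric(tb) / length(f))
  }
  list(distances = dist_out, matched_freq = matched_freq,
       matched_spectrum = bin_table(matched_freq),
       null_spectrum = bin_table(null_freq), n_skipped = n_skipped)
}

#' Expected exact-match fraction by allele-frequency bin
#'
#' Models the probability that an allele of frequency f has at least one
#' exact match among the m external reads at its locus when a fraction c of
#' the external sample is identical with the population:
#' p = 1 - (1 - c f)^m. Per half-log frequency bin, the expected matched
#' fraction and a normal-approximation prediction band for the sum of
#' independent Bernoulli(p_a) over alleles are reported, with observed
#' fractions overlaid when reads are supplied.
#'
#' @param tables named list of [locus_table]
#' @param reads data.frame(sequence, locus_id) of external reads (may have
#'   zero rows: model only)
#' @param match_rate_c identical fraction c in (0, 1]
#' @param ci_level prediction-band level
#' @return data.frame: bin, n_alleles, expected, lower, upper, observed
#' @export
exact_match_curve <- function(tables, reads, match_rate_c, ci_level = 0.99) {
  stopifnot(match_rate_c >= 0, match_rate_c <= 1)
  f_all <- numeric(0); p_all <- numeric(0); match_all <- logical(0)
  for (loc in names(tables)) {
    tb <- tables[[loc]]
    rr <- reads[reads$locus_id == loc, , drop = FALSE]
    m <- nrow(rr)
    f <- tb$alleles$frequency
    p <- 1 - (1 - match_rate_c * f)^m
    obs <- tb$alleles$sequence %in% rr$sequence
    f_all <- c(f_all, f); p_all <- c(p_all, p); match_all <- c(match_all, obs)
  }
  bins <- half_log_bin(f_all)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- list()
  for (b in sort(unique(bins))) {
    sel <- bins == b
    n <- sum(sel)
    mu <- mean(p_all[sel])
    v <- sum(p_all[sel] * (1 - p_all[sel])) / n^2
    out[[length(out) + 1]] <- data.frame(
      bin = b, n_alleles = n, expected = mu,
      lower = max(0, mu - z * sqrt(v)), upper = min(1, mu + z * sqrt(v)),
      observed = mean(match_all[sel]))
  }
  do.call(rbind, out)
}
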