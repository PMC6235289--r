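# Site classification, transition-dimorph extraction, depth-conditioned
# site-frequency spectra, neutral and deleterious expectations, and
# composition summaries.
#
# All spectra use the polarized frequency f_A/T of the A-or-T variant of a
# transition dimorph (A<->G or C<->T): each transition pairs exactly one
# A/T nucleotide with one G/C nucleotide, so the polarization is always
# defined (asserted below) and is strand-symmetric.

SITE_CLASSES <- c("syn_third", "syn_first_LRS", "nonsyn_second",
                  "intergenic", "excluded")

#' Classify reference-based columns of a locus by functional site class
#'
#' Columns where the reference (ref_b) carries a base are assigned exactly
#' one class. Within the designated CDS: second codon positions are
#' non-synonymous representatives; third positions are synonymous provided
#' the most common amino acid at the codon (read-weighted, among alleles
#' with an ungapped codon) is not M, W, or Stop, with nucleotide counts
#' restricted to alleles whose codon encodes that amino acid; first
#' positions are synonymous representatives only for codons whose most
#' common amino acid is L, R, or S (again counting only matching alleles).
#' Columns outside every coding interval are intergenic; everything else
#' (first positions of other codons, non-designated coding sequence,
#' reference gaps) is excluded.
#'
#' @param table a [locus_table] with ref_b and a designated CDS (loci
#'   without any coding interval are fully intergenic)
#' @return data.frame of class `site_classification`: position (1-based
#'   locus coordinate), class, A/C/G/T read counts among qualifying alleles,
#'   depth R
#' @export
classify_sites <- function(table) {
  if (is.null(table$ref_b)) stop("classify_sites requires ref_b")
  L <- table$L
  ref_chars <- strsplit(table$ref_b, "")[[1]]
  seq_mat <- seq_matrix(table$alleles$sequence)
  reads <- table$alleles$read_count
  cls <- rep("excluded", L)
  counts <- matrix(0L, L, 4, dimnames = list(NULL, NUCS))
  R <- integer(L)
  coding_mask <- rep(FALSE, L)
  if (!is.null(table$coding_intervals)) {
    for (r in seq_len(nrow(table$coding_intervals)))
      coding_mask[(table$coding_intervals$start[r] + 1):
                    table$coding_intervals$end[r]] <- TRUE
  }
  count_at <- function(col, allele_sel) {
    bases <- seq_mat[allele_sel, col]
    ok <- bases %in% NUCS
    vapply(NUCS, function(b) sum(reads[allele_sel][ok & bases == b]), 0L)
  }
  # intergenic and default counts
  for (col in seq_len(L)) {
    if (ref_chars[col] == "-") next       # reference gap: excluded
    if (!coding_mask[col]) {
      cls[col] <- "intergenic"
      cc <- count_at(col, rep(TRUE, nrow(seq_mat)))
      counts[col, ] <- cc
      R[col] <- sum(cc)
    }
  }
  if (!is.na(table$designated_cds)) {
    interval <- designated_interval(table)
    # per-allele codons in transcription orientation
    allele_codons <- lapply(table$alleles$sequence, function(s) {
      ch <- cds_chars(s, interval)
      split_codons(paste(ch, collapse = ""))
    })
    n_codons <- length(allele_codons[[1]])
    # locus column of (codon k, codon position p) in transcription orientation
    col_of <- function(k, p) {
      off <- 3 * (k - 1) + (p - 1) + interval$frame
      if (interval$strand == "+") interval$start + off + 1 else
        interval$end - off
    }
    for (k in seq_len(n_codons)) {
      codons_k <- vapply(allele_codons, `[`, "", k)
      valid <- !grepl("[^ACGT]", codons_k)
      aa_k <- rep(NA_character_, length(codons_k))
      aa_k[valid] <- translate_codon(codons_k[valid])
      cols <- vapply(1:3, function(p) col_of(k, p), 0)
      if (any(ref_chars[cols] == "-")) next
      # most common amino acid by read weight
      top_aa <- NA_character_
      if (any(valid)) {
        wt <- tapply(reads[valid], aa_k[valid], sum)
        top_aa <- names(wt)[order(-wt, names(wt))][1]
      }
      match_sel <- valid & !is.na(aa_k) & aa_k == top_aa
      # position 2: always non-synonymous
      c2 <- cols[2]
      cls[c2] <- "nonsyn_second"
      cc <- count_at(c2, rep(TRUE, nrow(seq_mat)))
      counts[c2, ] <- cc; R[c2] <- sum(cc)
      # position 3: synonymous unless top aa is M, W, Stop, or undefined
      if (!is.na(top_aa) && !(top_aa %in% c("M", "W", "*"))) {
        c3 <- cols[3]
        cls[c3] <- "syn_third"
        cc <- count_at(c3, match_sel)
        counts[c3, ] <- cc; R[c3] <- sum(cc)
      }
      # position 1: synonymous pairs used for L, R, S
      if (!is.na(top_aa) && top_aa %in% c("L", "R", "S")) {
        c1 <- cols[1]
        cls[c1] <- "syn_first_LRS"
        cc <- count_at(c1, match_sel)
        counts[c1, ] <- cc; R[c1] <- sum(cc)
      }
    }
  }
  out <- data.frame(position = seq_len(L), class = cls, counts, R = R,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_classification", class(out))
  out
}

#' Extract polarized transition dimorphs from a site classification
#'
#' Keeps sites with exactly two observed nucleotides forming a transition
#' pair (A/G or C/T); sites that are monomorphic, transversion-dimorphic, or
#' carry more than two variants are dropped with the reason tallied.
#'
#' @param classification a [classify_sites] result
#' @param min_count minimum read count of the minor variant
#' @param classes site classes to keep
#' @return data.frame of class `dimorph_sites`: position, class, variant
#'   pair, f_AT, R; attribute `dropped` tallies exclusion reasons
#' @export
extract_transition_dimorphs <- function(classification, min_count = 1,
                                        classes = setdiff(SITE_CLASSES,
                                                          "excluded")) {
  keep <- classification$class %in% classes & classification$R > 0
  cc <- classification[keep, , drop = FALSE]
  dropped <- c(monomorphic = 0L, transversion = 0L, multi_variant = 0L,
               low_count = 0L)
  rows <- list()
  for (r in seq_len(nrow(cc))) {
    nb <- as.integer(cc[r, NUCS])
    present <- NUCS[nb > 0]
    if (length(present) < 2) { dropped["monomorphic"] <- dropped["monomorphic"] + 1L; next }
    if (length(present) > 2) { dropped["multi_variant"] <- dropped["multi_variant"] + 1L; next }
    if (unname(TRANSITION_PARTNER[present[1]]) != present[2]) {
      dropped["transversion"] <- dropped["transversion"] + 1L; next
    }
    at <- present[present %in% c("A", "T")]
    gc <- present[present %in% c("G", "C")]
    stopifnot(length(at) == 1, length(gc) == 1)  # transition polarization
    n_at <- nb[match(at, NUCS)]; n_gc <- nb[match(gc, NUCS)]
    if (min(n_at, n_gc) < min_count) { dropped["low_count"] <- dropped["low_count"] + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      position = cc$position[r], class = cc$class[r],
      pair = paste0(at, "/", gc), f_AT = n_at / (n_at + n_gc),
      R = n_at + n_gc, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(position = integer(0), class = character(0),
               pair = character(0), f_AT = numeric(0), R = integer(0))
  class(out) <- c("dimorph_sites", class(out))
  attr(out, "dropped") <- dropped
  out
}

logistic <- function(l) 1 / (1 + exp(-l))

ell_bin_edges <- function(f) floor(log(f / (1 - f)))

pow2_bin_edges <- function() {
  k <- 1
  edges <- 2^-1
  while (edges[length(edges)] >= 1e-3) {
    k <- k + 1
    edges <- c(edges, 2^-k)
  }
  edges   # descending: 1/2, 1/4, ..., first edge below 1e-3
}

#' Bin a set of dimorph frequencies into a site-frequency spectrum
#'
#' Three conventions: `ell_sfs` - unit bins with integer edges in
#' l = log(f/(1-f)) (natural log), counts divided by (bin width in f) times
#' the number of sites deep enough to resolve the bin (R > 1 / the bin's
#' smaller minor-frequency edge); `ell_histogram` - plain normalized
#' histogram of l, no depth conditioning; `minor_pow2` - minor-frequency
#' bins with edges 1/2, 1/4, ... down past 1e-3, counts divided by the
#' total number of sites.
#'
#' @param dimorphs a [extract_transition_dimorphs] result (or data.frame
#'   with f_AT and R)
#' @param binning one of "ell_sfs", "ell_histogram", "minor_pow2"
#' @param site_depths depths R of ALL candidate sites of the class
#'   (including monomorphic ones) for the eligibility denominators; defaults
#'   to the dimorph depths only
#' @return data.frame of class `binned_sfs`: bin_low, bin_high (f for
#'   ell_sfs/minor_pow2 given on the f scale via `f_low`, `f_high`), value,
#'   n_snps, n_eligible_sites; attribute `binning`
#' @export
sfs_binned <- function(dimorphs, binning = c("ell_sfs", "ell_histogram",
                                             "minor_pow2"),
                       site_depths = dimorphs$R) {
  binning <- match.arg(binning)
  f <- dimorphs$f_AT
  out <- NULL
  if (binning %in% c("ell_sfs", "ell_histogram")) {
    if (length(f) == 0) {
      out <- data.frame(bin_low = numeric(0), bin_high = numeric(0),
                        f_low = numeric(0), f_high = numeric(0),
                        value = numeric(0), n_snps = integer(0),
                        n_eligible_sites = integer(0))
    } else {
      b <- ell_bin_edges(f)
      bins <- sort(unique(b))
      rows <- lapply(bins, function(lo) {
        hi <- lo + 1
        n <- sum(b == lo)
        f_lo <- logistic(lo); f_hi <- logistic(hi)
        if (binning == "ell_histogram") {
          val <- n / length(f)
          elig <- length(site_depths)
        } else {
          min_edge <- min(f_lo, 1 - f_hi)
          elig <- sum(site_depths > 1 / min_edge)
          val <- if (elig > 0) n / ((f_hi - f_lo) * elig) else NA_real_
        }
        data.frame(bin_low = lo, bin_high = hi, f_low = f_lo, f_high = f_hi,
                   value = val, n_snps = n, n_eligible_sites = elig)
      })
      out <- do.call(rbind, rows)
    }
  } else {
    fm <- pmin(f, 1 - f)
    edges <- pow2_bin_edges()
    rows <- list()
    for (k in seq_len(length(edges) - 1)) {
      hi <- edges[k]; lo <- edges[k + 1]
      n <- sum(fm < hi & fm >= lo)
      rows[[k]] <- data.frame(bin_low = lo, bin_high = hi, f_low = lo,
                              f_high = hi,
                              value = n / max(length(site_depths), 1),
                              n_snps = n,
                              n_eligible_sites = length(site_depths))
    }
    out <- do.call(rbind, rows)
  }
  class(out) <- c("binned_sfs", class(out))
  attr(out, "binning") <- binning
  out
}

#' Beta-binomial sampling distribution of the neutral site-frequency spectrum
#'
#' P(x | R, theta) = C(R, x) B(x + theta, R - x + theta) / B(theta, theta),
#' the read-sampling mixture of the equilibrium neutral drift spectrum
#' rho(f) = [f(1-f)]^(theta-1) / B(theta, theta).
#'
#' @param theta scaled mutation rate of the spectrum
#' @param R read depth
#' @return numeric vector of probabilities for x = 0..R
#' @export
beta_binomial_pmf <- function(theta, R) {
  x <- 0:R
  exp(lchoose(R, x) + lbeta(x + theta, R - x + theta) - lbeta(theta, theta))
}

#' Expected binned SFS under neutral drift with read-depth sampling
#'
#' Sums the polymorphic part (x = 1..R-1) of the beta-binomial over the
#' supplied per-site depths and bins the expected counts exactly as
#' [sfs_binned] bins the data.
#'
#' @param theta scaled mutation rate
#' @param depths per-site read depths
#' @param binning as in [sfs_binned]
#' @return `binned_sfs` data.frame of expected values
#' @export
neutral_sfs_expectation <- function(theta, depths,
                                    binning = c("ell_sfs", "ell_histogram",
                                                "minor_pow2")) {
  binning <- match.arg(binning)
  stopifnot(theta > 0, all(depths >= 2))
  # accumulate expected mass per (f = x/R) value
  f_vals <- numeric(0); mass <- numeric(0);
  for (R in unique(depths)) {
    nR <- sum(depths == R)
    p <- beta_binomial_pmf(theta, R)
    x <- 1:(R - 1)
    f_vals <- c(f_vals, x / R)
    mass <- c(mass, nR * p[x + 1])
  }
  total_poly <- sum(mass)
  if (binning %in% c("ell_sfs", "ell_histogram")) {
    b <- ell_bin_edges(f_vals)
    bins <- sort(unique(b))
    rows <- lapply(bins, function(lo) {
      hi <- lo + 1
      m <- sum(mass[b == lo])
      f_lo <- logistic(lo); f_hi <- logistic(hi)
      if (binning == "ell_histogram") {
        val <- m / total_poly
        elig <- length(depths)
      } else {
        min_edge <- min(f_lo, 1 - f_hi)
        elig <- sum(depths > 1 / min_edge)
        val <- if (elig > 0) m / ((f_hi - f_lo) * elig) else NA_real_
      }
      data.frame(bin_low = lo, bin_high = hi, f_low = f_lo, f_high = f_hi,
                 value = val, n_snps = m, n_eligible_sites = elig)
    })
    out <- do.call(rbind, rows)
  } else {
    fm <- pmin(f_vals, 1 - f_vals)
    edges <- pow2_bin_edges()
    rows <- list()
    for (k in seq_len(length(edges) - 1)) {
      hi <- edges[k]; lo <- edges[k + 1]
      m <- sum(mass[fm < hi & fm >= lo])
      rows[[k]] <- data.frame(bin_low = lo, bin_high = hi, f_low = lo,
                              f_high = hi, value = m / length(depths),
                              n_snps = m, n_eligible_sites = length(depths))
    }
    out <- do.call(rbind, rows)
  }
  class(out) <- c("binned_sfs", class(out))
  attr(out, "binning") <- binning
  out
}

#' Ratio of non-synonymous to synonymous SFS by minor-frequency bin
#'
#' @param ns_sfs,syn_sfs `binned_sfs` results on the minor_pow2 binning,
#'   each normalized by its own site total
#' @return data.frame: bin_low, bin_high, ratio (NA where the synonymous
#'   bin is empty)
#' @export
ns_syn_ratio <- function(ns_sfs, syn_sfs) {
  if (!identical(attr(ns_sfs, "binning"), "minor_pow2") ||
      !identical(attr(syn_sfs, "binning"), "minor_pow2"))
    stop("ns_syn_ratio requires both spectra on the minor_pow2 binning")
  if (!isTRUE(all.equal(ns_sfs$bin_low, syn_sfs$bin_low)))
    stop("mismatched bins")
  data.frame(bin_low = ns_sfs$bin_low, bin_high = ns_sfs$bin_high,
             ratio = ifelse(syn_sfs$value > 0,
                            ns_sfs$value / syn_sfs$value, NA_real_))
}

#' Selection parameters for the deleterious SFS
#' @param s selective disadvantage per generation (>= 0)
#' @param T_M mean coalescent time in generations (> 0)
#' @return list of class `selection_params`
#' @export
selection_params <- function(s, T_M) {
  stopifnot(s >= 0, T_M > 0)
  structure(list(s = s, T_M = T_M), class = "selection_params")
}

#' Deleterious site-frequency spectrum
#'
#' rho_s(f) = exp(-s f T_M) * rho_0(f) with the small-theta neutral form
#' rho_0(f) = theta / (2 f (1 - f)).
#'
#' @param params a [selection_params]
#' @param theta scaled mutation rate
#' @param f_grid frequencies in (0, 1)
#' @return numeric density on the grid
#' @export
deleterious_sfs <- function(params, theta, f_grid) {
  stopifnot(all(f_grid > 0), all(f_grid < 1))
  exp(-params$s * f_grid * params$T_M) * theta / (2 * f_grid * (1 - f_grid))
}

#' AT:GC composition of fixed (monomorphic) sites by class
#'
#' @param classification a [classify_sites] result
#' @return data.frame per class: n_AT, n_GC, gc_fraction
#' @export
fixed_site_composition <- function(classification) {
  cc <- classification[classification$class != "excluded" &
                         classification$R > 0, , drop = FALSE]
  out <- list()
  for (cl in unique(cc$class)) {
    sub <- cc[cc$class == cl, , drop = FALSE]
    nb <- as.matrix(sub[, NUCS])
    mono <- rowSums(nb > 0) == 1
    base <- NUCS[apply(nb[mono, , drop = FALSE], 1, which.max)]
    n_at <- sum(base %in% c("A", "T")); n_gc <- sum(base %in% c("G", "C"))
    out[[cl]] <- data.frame(class = cl, n_AT = n_at, n_GC = n_gc,
                            gc_fraction = if (n_at + n_gc > 0)
                              n_gc / (n_at + n_gc) else NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
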