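# Synthetic loci with coding structure, controllable dn/ds, and a 454-style
# sequencing-error overlay; inputs with known truth for the false-negative
# solver.

#' Amplicon sequencing-error model
#'
#' Substitution errors are i.i.d. across sites and reads with a 4x4 rate
#' matrix lambda (row = true base, column = observed base) scaled so the
#' expected number of substitution errors on a read of length `L` is
#' `total_sub_rate`. Transitions are weighted `kappa`-fold over each
#' transversion, mirroring amplicon error spectra. Indel errors in coding
#' sequence follow a position-dependent exponential profile
#' rate(pos) = a * exp(b * pos), with (a, b) solved so the per-site rate at
#' position `L` is `indel_coding_end` and the read-average rate is
#' `indel_coding_mean`; intergenic indel errors occur at a constant rate.
#'
#' @param total_sub_rate expected substitution errors per read
#' @param L read length the rate is normalized to
#' @param kappa transition:transversion weight of the error matrix
#' @param indel_coding_end per-site coding indel-error rate at position L
#' @param indel_coding_mean read-average coding indel-error rate per site
#' @param indel_intergenic_rate constant per-site intergenic indel rate
#' @return object of class `error_model` with `lambda_sub` (per site per
#'   read), `p_site` (total substitution rate by true base),
#'   `indel_coding_rate(position)` and `indel_intergenic_rate`
#' @export
error_model <- function(total_sub_rate = 0.63, L = 400, kappa = 10,
                        indel_coding_end = 0.01, indel_coding_mean = 0.005,
                        indel_intergenic_rate = 0.005) {
  stopifnot(total_sub_rate >= 0, L >= 1)
  W <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  for (a in NUCS) for (b in NUCS) {
    if (a == b) next
    W[a, b] <- if (unname(TRANSITION_PARTNER[a]) == b) kappa else 0.5
  }
  # per-site per-read rates; every base has the same total error rate
  lambda <- W / rowSums(W) * (total_sub_rate / L)
  ab <- c(a = 0, b = 0)
  if (indel_coding_end > 0) {
    ratio <- indel_coding_end / indel_coding_mean
    # solve x/(1 - exp(-x)) = ratio for x = b*L
    f <- function(x) x / (1 - exp(-x)) - ratio
    x <- if (ratio > 1) stats::uniroot(f, c(1e-8, 50))$root else 1e-8
    ab <- c(a = indel_coding_end * exp(-x), b = x / L)
  }
  structure(list(lambda_sub = lambda, p_site = rowSums(lambda),
                 total_sub_rate = total_sub_rate, L = L, kappa = kappa,
                 indel_coding_rate = function(position)
                   ab["a"] * exp(ab["b"] * position),
                 indel_coding_ab = ab,
                 indel_intergenic_rate = indel_intergenic_rate),
            class = "error_model")
}

# Enumeration over single-base changes of a CDS, weighted by `weights`
# (a 4x4 from->to matrix): rates of synonymous and non-synonymous change
# plus Nei-Gojobori (equal-weight) site counts.
cds_change_rates <- function(cds_codons, weights) {
  syn_rate <- ns_rate <- 0
  S_sites <- N_sites <- 0
  for (codon in cds_codons) {
    if (grepl("[^ACGT]", codon)) next
    aa0 <- translate_codon(codon)
    vars <- single_base_variants(codon)
    syn <- translate_codon(vars$codon) == aa0
    w <- weights[cbind(vars$from, vars$to)]
    syn_rate <- syn_rate + sum(w[syn])
    ns_rate <- ns_rate + sum(w[!syn])
    # equal-weight NG site fractions
    S_sites <- S_sites + sum(syn) / 3
    N_sites <- N_sites + sum(!syn) / 3
  }
  list(syn_rate = syn_rate, ns_rate = ns_rate,
       S_sites = S_sites, N_sites = N_sites)
}

#' Non-synonymous thinning probability for a target dn/ds
#'
#' Solves for the acceptance probability q applied to candidate
#' non-synonymous mutations so that the expected counting-method dn/ds over
#' the ancestral codon composition equals `target_dnds`.
#'
#' @param target_dnds desired expected dn/ds (>= 0)
#' @param cds_codons ancestral codons (composition reference)
#' @param rates mutation-rate structure from [mutation_rates]
#' @return q in [0, 1]
#' @export
ns_thinning_prob <- function(target_dnds, cds_codons, rates) {
  stopifnot(target_dnds >= 0)
  if (target_dnds == 0) return(0)
  cr <- cds_change_rates(cds_codons, rates$W)
  if (cr$ns_rate == 0) return(1)
  # realized d_s ~ syn_rate/S_sites, d_n ~ q * ns_rate/N_sites
  q <- target_dnds * (cr$syn_rate / cr$S_sites) / (cr$ns_rate / cr$N_sites)
  min(q, 1)
}

# random stop-free ancestral sequence whose first cds_len sites are coding
random_coding_ancestral <- function(L, cds_len, pi) {
  repeat {
    anc <- sample(NUCS, L, replace = TRUE, prob = pi)
    if (cds_len == 0) return(paste(anc, collapse = ""))
    codons <- split_codons(paste(anc[1:cds_len], collapse = ""))
    bad <- translate_codon(codons) == "*"
    if (!any(bad)) return(paste(anc, collapse = ""))
    for (k in which(bad)) {
      repeat {
        cand <- sample(NUCS, 3, replace = TRUE, prob = pi)
        if (translate_codon(paste(cand, collapse = "")) != "*") break
      }
      anc[(3 * k - 2):(3 * k)] <- cand
    }
    return(paste(anc, collapse = ""))
  }
}

#' Generate a synthetic coding locus with controlled dn/ds
#'
#' Samples a coalescent genealogy, overlays K2P mutations, and classifies
#' every candidate mutation in the coding region as synonymous or
#' non-synonymous against the current codon of its descendant leaf set;
#' non-synonymous candidates are accepted with probability q calibrated from
#' `target_dnds` via [ns_thinning_prob].
#'
#' @param config a [sim_config]; `config$n` is the read depth
#' @param coding_fraction fraction of the locus that is coding (rounded down
#'   to whole codons, placed at the left end)
#' @param target_dnds expected dn/ds of the generated coding diversity
#' @param depth number of leaves (must equal config$n)
#' @param locus_id identifier
#' @return list with `table` (a [locus_table] with annotated designated CDS)
#'   and `truth` (generator bookkeeping: ancestral, q, candidate and accepted
#'   mutation counts by class)
#' @export
generate_coding_locus <- function(config, coding_fraction = 1,
                                  target_dnds = 0.12, depth = config$n,
                                  locus_id = "simcds") {
  stopifnot(coding_fraction >= 0, coding_fraction <= 1, depth == config$n)
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$L
  cds_len <- 3L * as.integer(floor(L * coding_fraction / 3))
  rates <- mutation_rates(config$theta, config$kappa, config$gc_bias)
  anc <- if (identical(config$ancestral, "random"))
    random_coding_ancestral(L, cds_len, rates$pi) else config$ancestral
  anc_chars <- strsplit(anc, "")[[1]]
  q <- if (cds_len > 0)
    ns_thinning_prob(target_dnds,
                     split_codons(substr(anc, 1, cds_len)), rates) else 1
  cfg <- config; cfg$seed <- NULL; cfg$ancestral <- anc
  gen <- sample_genealogy(cfg)
  n <- gen$n
  seqs <- matrix(rep(anc_chars, each = n), nrow = n)
  book <- c(syn = 0L, nonsyn_kept = 0L, nonsyn_dropped = 0L, noncoding = 0L)
  if (rates$mu_max > 0) {
    mut_site <- integer(0); mut_time <- numeric(0); mut_branch <- integer(0)
    for (bi in seq_along(gen$branches)) {
      b <- gen$branches[[bi]]
      if (is.na(b$t1)) next
      nsites <- if (is.null(b$groups)) L else sum(b$groups > 0L)
      nm <- stats::rpois(1, rates$mu_max * nsites * (b$t1 - b$t0))
      if (nm == 0) next
      sites <- if (is.null(b$groups)) sample.int(L, nm, replace = TRUE) else
        which(b$groups > 0L)[sample.int(nsites, nm, replace = TRUE)]
      mut_site <- c(mut_site, sites)
      mut_time <- c(mut_time, stats::runif(nm, b$t0, b$t1))
      mut_branch <- c(mut_branch, rep(bi, nm))
    }
    for (m in order(mut_time, decreasing = TRUE)) {
      b <- gen$branches[[mut_branch[m]]]
      s <- mut_site[m]
      leaves <- if (is.null(b$groups)) b$leaves else b$leafsets[[b$groups[s]]]
      cur <- seqs[leaves[1], s]
      if (stats::runif(1) > rates$mu[cur] / rates$mu_max) next
      target <- sample(NUCS, 1, prob = rates$W[cur, ])
      if (s <= cds_len) {
        ci <- (s - 1) %/% 3
        idx <- (3 * ci + 1):(3 * ci + 3)
        old_codon <- paste(seqs[leaves[1], idx], collapse = "")
        new_chars <- seqs[leaves[1], idx]
        new_chars[s - 3 * ci] <- target
        new_codon <- paste(new_chars, collapse = "")
        if (translate_codon(old_codon) == translate_codon(new_codon)) {
          book["syn"] <- book["syn"] + 1L
        } else if (stats::runif(1) <= q) {
          book["nonsyn_kept"] <- book["nonsyn_kept"] + 1L
        } else {
          book["nonsyn_dropped"] <- book["nonsyn_dropped"] + 1L
          next
        }
      } else {
        book["noncoding"] <- book["noncoding"] + 1L
      }
      seqs[leaves, s] <- target
    }
  }
  reads <- apply(seqs, 1, paste, collapse = "")
  ci <- if (cds_len > 0)
    data.frame(start = 0L, end = cds_len, strand = "+", frame = 0L,
               hypothetical = 0L) else NULL
  tb <- collapse_reads_to_table(reads, locus_id, ref_b = anc,
                                coding_intervals = ci)
  if (!is.null(ci)) tb$designated_cds <- 1L
  list(table = tb,
       truth = list(ancestral = anc, q = q, cds_len = cds_len,
                    mutation_counts = book))
}

#' Overlay sequencing errors on a locus allele table
#'
#' Draws `n_reads` reads from the alleles with probability equal to allele
#' frequency, then applies i.i.d. substitution errors per the error model's
#' lambda matrix and position-dependent indel errors (realized as single-base
#' deletions in the reference frame: coding positions follow the exponential
#' profile, intergenic positions the constant rate).
#'
#' @param table a [locus_table]
#' @param model an [error_model]
#' @param n_reads number of raw reads to emit (default: table depth)
#' @param seed optional integer seed
#' @return list with `reads` (character vector), `truth` (data.frame:
#'   read index, source allele index, substitution and indel error counts)
#' @export
add_sequencing_errors <- function(table, model, n_reads = table$depth,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- table$L
  coding <- rep(FALSE, L)
  if (!is.null(table$coding_intervals)) {
    for (r in seq_len(nrow(table$coding_intervals)))
      coding[(table$coding_intervals$start[r] + 1):
               table$coding_intervals$end[r]] <- TRUE
  }
  pos <- seq_len(L)
  indel_rate <- ifelse(coding, model$indel_coding_rate(pos),
                       model$indel_intergenic_rate)
  src <- sample.int(nrow(table$alleles), n_reads, replace = TRUE,
                    prob = table$alleles$frequency)
  reads <- character(n_reads)
  n_sub <- integer(n_reads); n_ind <- integer(n_reads)
  lam <- model$lambda_sub
  p_site <- model$p_site
  for (r in seq_len(n_reads)) {
    chars <- strsplit(table$alleles$sequence[src[r]], "")[[1]]
    base_ok <- chars %in% NUCS
    p <- ifelse(base_ok, p_site[match(chars, NUCS)], 0)
    hit <- which(stats::runif(L) < p)
    for (s in hit)
      chars[s] <- sample(NUCS, 1, prob = lam[chars[s], ])
    ind <- which(stats::runif(L) < indel_rate & base_ok)
    chars[ind] <- "-"
    reads[r] <- paste(chars, collapse = "")
    n_sub[r] <- length(setdiff(hit, ind))
    n_ind[r] <- length(ind)
  }
  list(reads = reads,
       truth = data.frame(read = seq_len(n_reads), source_allele = src,
                          n_sub = n_sub, n_indel = n_ind))
}

FN_STRATA <- c("singleton", "multi1", "double2")

# (n_reads, d) cells of the three putative-error strata:
# singleton reads with 1..7 CDS substitutions; 2-10-read sequences with one
# CDS substitution; two-read sequences with two CDS substitutions.
fn_strata_cells <- function() {
  rbind(data.frame(stratum = "singleton", n_reads = 1L, d = 1:7),
        data.frame(stratum = "multi1", n_reads = 2:10, d = 1L),
        data.frame(stratum = "double2", n_reads = 2L, d = 2L))
}

#' Synonymous fraction expected of genuine (false-negative) differences
#'
#' Under the internal error-normalized definition of dn/ds, a genuine
#' difference is synonymous with probability
#' q = p_S / (p_S + dnds * (1 - p_S)).
#' @param p_S probability an error is synonymous
#' @param dnds assumed dn/ds of genuine diversity
#' @return probability in (0, 1]
#' @export
fn_syn_prob <- function(p_S, dnds) p_S / (p_S + dnds * (1 - p_S))

#' Generate a synthetic putative-error class table with planted false negatives
#'
#' Builds counts s_{i,d}^{(n)} (i of the d coding substitutions synonymous)
#' as a mixture of true errors, binomial(d, p_S) in i, and planted genuine
#' false negatives, binomial(d, q) with q from [fn_syn_prob].
#'
#' @param n_genuine_fn planted false negatives per stratum: length-3 vector
#'   (singleton, multi1, double2) or a scalar planted entirely in the
#'   multi-read stratum
#' @param fn_dnds dn/ds of the planted genuine sequences
#' @param p_S synonymous-error probability
#' @param n_errors_by_class true-error totals per stratum (length-3 vector)
#' @param seed optional integer seed
#' @return list with `table` (data.frame n_reads, d, i, count of class
#'   `error_class_table`) and `truth` (per-cell split into errors x and
#'   genuine r)
#' @export
generate_error_class_table <- function(n_genuine_fn, fn_dnds, p_S,
                                       n_errors_by_class, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_genuine_fn) == 1)
    n_genuine_fn <- c(0, n_genuine_fn, 0)
  stopifnot(length(n_genuine_fn) == 3, length(n_errors_by_class) == 3)
  names(n_genuine_fn) <- names(n_errors_by_class) <- FN_STRATA
  q <- fn_syn_prob(p_S, fn_dnds)
  cells <- fn_strata_cells()
  rows <- list(); truth <- list()
  for (st in FN_STRATA) {
    sub <- cells[cells$stratum == st, , drop = FALSE]
    # spread stratum totals over cells: geometric in d, inverse in n_reads
    w <- (0.5^sub$d) / sub$n_reads
    w <- w / sum(w)
    x_cell <- as.vector(stats::rmultinom(1, n_errors_by_class[st], w))
    r_cell <- as.vector(stats::rmultinom(1, n_genuine_fn[st], w))
    for (k in seq_len(nrow(sub))) {
      d <- sub$d[k]
      xi <- as.vector(stats::rmultinom(1, x_cell[k], stats::dbinom(0:d, d, p_S)))
      ri <- as.vector(stats::rmultinom(1, r_cell[k], stats::dbinom(0:d, d, q)))
      rows[[length(rows) + 1]] <-
        data.frame(n_reads = sub$n_reads[k], d = d, i = 0:d, count = xi + ri)
      truth[[length(truth) + 1]] <-
        data.frame(stratum = st, n_reads = sub$n_reads[k], d = d, i = 0:d,
                   x = xi, r = ri)
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("error_class_table", class(tab))
  list(table = tab, truth = do.call(rbind, truth))
}
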