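# Synonymous-error probability, false-negative mixture solving, FN set
# sampling, and positional indel-rate profiling.

#' Probability that a substitution error is synonymous
#'
#' Enumerates all single-base errors over the reference coding sequence,
#' weighted by the substitution-rate matrix, and returns the synonymous
#' fraction.
#'
#' @param ref_cds coding nucleotide string (in frame, length a multiple of 3)
#'   or a character vector of codons
#' @param lambda_sub 4x4 substitution-rate matrix (row = true base)
#' @return p_S in [0, 1]
#' @export
synonymous_error_probability <- function(ref_cds, lambda_sub) {
  codons <- if (length(ref_cds) == 1 && nchar(ref_cds[1]) > 3)
    split_codons(ref_cds) else ref_cds
  cr <- cds_change_rates(codons, lambda_sub)
  tot <- cr$syn_rate + cr$ns_rate
  if (tot == 0) return(0)
  cr$syn_rate / tot
}

# two-variable non-negative least squares of s ~ x*a + r*b
nnls2 <- function(s, a, b) {
  A <- cbind(a, b)
  G <- crossprod(A)
  if (abs(det(G)) > 1e-12) {
    sol <- solve(G, crossprod(A, s))
    if (all(sol >= 0)) return(c(x = sol[1], r = sol[2]))
  }
  # clamp each variable to zero, keep the better non-negative 1-D solution
  x_only <- max(0, sum(a * s) / sum(a * a))
  r_only <- max(0, sum(b * s) / sum(b * b))
  res_x <- sum((s - x_only * a)^2)
  res_r <- sum((s - r_only * b)^2)
  if (res_x <= res_r) c(x = x_only, r = 0) else c(x = 0, r = r_only)
}

#' Solve the error / false-negative mixture of a putative-error class table
#'
#' Within each (n reads, d coding substitutions) cell, the counts
#' s_i (i synonymous of d) are modeled as x_tot * Binom(i; d, p_S) true
#' errors plus r_tot * Binom(i; d, q) genuine false negatives, with q the
#' synonymous fraction implied by the assumed dn/ds of genuine sequences
#' ([fn_syn_prob]). d = 1 cells are solved exactly (2 equations, 2
#' unknowns); d >= 2 cells by non-negative least squares. Components are
#' clipped to [0, s_i] with the remainder re-attributed, so x + r = s
#' element-wise.
#'
#' @param table an `error_class_table` data.frame (n_reads, d, i, count)
#' @param p_S synonymous-error probability in (0, 1)
#' @param target_dnds assumed dn/ds of genuine diversity (the degenerate
#'   case target_dnds = 1 makes the mixture non-identifiable and errors)
#' @return object of class `fn_solution`: per-cell data.frame (n_reads, d,
#'   i, s, x, r), stratum totals, p_S and q used
#' @export
solve_fn_mixture <- function(table, p_S, target_dnds) {
  stopifnot(p_S > 0, p_S < 1, target_dnds >= 0)
  q <- fn_syn_prob(p_S, target_dnds)
  if (abs(q - p_S) < 1e-9)
    stop("non-identifiable mixture: genuine dn/ds equals the pure-error ",
         "expectation (q = p_S), the two components have identical shapes")
  cells <- unique(table[, c("n_reads", "d")])
  rows <- list()
  infeasible <- FALSE
  for (k in seq_len(nrow(cells))) {
    d <- cells$d[k]; nr <- cells$n_reads[k]
    sub <- table[table$n_reads == nr & table$d == d, , drop = FALSE]
    sub <- sub[order(sub$i), , drop = FALSE]
    s <- rep(0, d + 1)
    s[sub$i + 1] <- sub$count
    a <- stats::dbinom(0:d, d, p_S)
    b <- stats::dbinom(0:d, d, q)
    if (d == 1) {
      # exact 2x2 solve
      M <- cbind(a, b)
      sol <- tryCatch(solve(M, s), error = function(e) NULL)
      tot <- if (is.null(sol)) nnls2(s, a, b) else
        c(x = unname(sol[1]), r = unname(sol[2]))
    } else {
      tot <- nnls2(s, a, b)
    }
    if (tot["x"] < 0 && tot["r"] < 0) infeasible <- TRUE
    x_i <- max(tot["x"], 0) * a
    r_i <- max(tot["r"], 0) * b
    # clip and re-attribute so x + r = s exactly
    r_i <- pmin(pmax(r_i, 0), s)
    x_i <- s - r_i
    neg <- x_i < 0
    r_i[neg] <- r_i[neg] + x_i[neg]
    x_i[neg] <- 0
    rows[[k]] <- data.frame(n_reads = nr, d = d, i = 0:d, s = s,
                            x = x_i, r = r_i)
  }
  if (infeasible)
    warning("infeasible cell(s): returned the all-error solution there")
  per_cell <- do.call(rbind, rows)
  strata <- fn_strata_cells()
  per_cell$stratum <- strata$stratum[match(paste(per_cell$n_reads, per_cell$d),
                                           paste(strata$n_reads, strata$d))]
  totals <- stats::aggregate(cbind(s, x, r) ~ stratum, data = per_cell, sum)
  structure(list(per_cell = per_cell, totals = totals, p_S = p_S, q = q,
                 target_dnds = target_dnds,
                 n_false_negatives = sum(per_cell$r)),
            class = "fn_solution")
}

#' Draw random false-negative sequence sets from a mixture solution
#'
#' Samples round(r) sequences uniformly without replacement within each
#' (n, d, i) cell; shortfalls take every available sequence and are logged.
#'
#' @param solution an [solve_fn_mixture] result
#' @param table_sequences data.frame(n_reads, d, i, seq_id) listing the
#'   candidate putative-error sequences per cell
#' @param seed optional integer seed
#' @return list: `fn_ids` (sampled sequence ids), `deficits` (cells where
#'   fewer sequences were available than requested)
#' @export
draw_fn_sets <- function(solution, table_sequences, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fn_ids <- character(0)
  deficits <- list()
  pc <- solution$per_cell
  for (k in seq_len(nrow(pc))) {
    want <- round(pc$r[k])
    if (want <= 0) next
    avail <- table_sequences$seq_id[
      table_sequences$n_reads == pc$n_reads[k] &
        table_sequences$d == pc$d[k] & table_sequences$i == pc$i[k]]
    if (length(avail) < want) {
      deficits[[length(deficits) + 1]] <-
        data.frame(n_reads = pc$n_reads[k], d = pc$d[k], i = pc$i[k],
                   wanted = want, available = length(avail))
      fn_ids <- c(fn_ids, avail)
    } else {
      fn_ids <- c(fn_ids, avail[sample.int(length(avail), want)])
    }
  }
  list(fn_ids = fn_ids,
       deficits = if (length(deficits) > 0) do.call(rbind, deficits) else NULL)
}

moving_average <- function(x, window) {
  n <- length(x)
  out <- rep(NA_real_, n)
  half <- window %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Per-position indel rates in coding vs intergenic sequence
#'
#' For raw reads and for denoised alleles (frequency-weighted), computes
#' the per-read per-site probability of an indel relative to the most
#' abundant allele at the same locus, split by site class and smoothed with
#' a moving average. Sequences more diverged than `divergence_cap` from the
#' most abundant allele are removed first.
#'
#' @param raw_reads data.frame(sequence, locus_id) of raw reads
#' @param tables named list of [locus_table]
#' @param window moving-average window (bp)
#' @param divergence_cap divergence screen against misalignment artifacts
#' @return data.frame: position, coding_raw, intergenic_raw,
#'   coding_denoised, intergenic_denoised (smoothed rates; NA where no
#'   sites of the class exist)
#' @export
indel_rate_profile <- function(raw_reads, tables, window = 25,
                               divergence_cap = 0.20) {
  L <- tables[[1]]$L
  num <- matrix(0, L, 4,
                dimnames = list(NULL, c("coding_raw", "intergenic_raw",
                                        "coding_denoised",
                                        "intergenic_denoised")))
  den <- matrix(0, L, 4, dimnames = dimnames(num))
  for (loc in names(tables)) {
    tb <- tables[[loc]]
    top <- tb$alleles$sequence[1]
    top_chars <- strsplit(top, "")[[1]]
    coding <- rep(FALSE, tb$L)
    if (!is.null(tb$coding_intervals))
      for (r in seq_len(nrow(tb$coding_intervals)))
        coding[(tb$coding_intervals$start[r] + 1):
                 tb$coding_intervals$end[r]] <- TRUE
    tally <- function(seqs, weights, kind) {
      ccol <- paste0("coding_", kind); icol <- paste0("intergenic_", kind)
      for (s in seq_along(seqs)) {
        if (fractional_divergence(seqs[s], top) > divergence_cap) next
        ch <- strsplit(seqs[s], "")[[1]]
        indel <- xor(ch == "-", top_chars == "-")
        w <- weights[s]
        num[coding, ccol] <<- num[coding, ccol] + w * indel[coding]
        den[coding, ccol] <<- den[coding, ccol] + w
        num[!coding, icol] <<- num[!coding, icol] + w * indel[!coding]
        den[!coding, icol] <<- den[!coding, icol] + w
      }
    }
    rr <- raw_reads[raw_reads$locus_id == loc, , drop = FALSE]
    if (nrow(rr) > 0) tally(rr$sequence, rep(1, nrow(rr)), "raw")
    tally(tb$alleles$sequence, tb$alleles$frequency, "denoised")
  }
  rate <- num / den
  rate[den == 0] <- NA
  smoothed <- apply(rate, 2, moving_average, window = window)
  data.frame(position = seq_len(L), smoothed)
}
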