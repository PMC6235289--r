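#' @importFrom stats rbinom rpois rexp rgamma runif rmultinom quantile median
#'   sd dbinom pbinom qnorm hclust cutree as.dist lm coef ks.test dist
#'   setNames aggregate
#' @importFrom utils head tail write.table read.table
NULL

NUCS <- c("A", "C", "G", "T")

# transitions: A<->G, C<->T
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(a, b) TRANSITION_PARTNER[a] == b

#' Genetic code used throughout (bacterial protein-coding translation)
#'
#' The standard codon table; bacterial usage differs only in initiation
#' codons, which play no role in per-codon difference counting.
#' @return named character vector mapping 64 codons to one-letter amino
#'   acids ("*" for stop).
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.codon_env <- new.env(parent = emptyenv())
.codon_env$variants <- new.env(parent = emptyenv())
.codon_env$ng_paths <- new.env(parent = emptyenv())
.codon_env$ng_sites <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- genetic_code()
  .codon_env$tab
}

translate_codon <- function(codon) {
  tab <- codon_table()
  aa <- tab[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Split a coding nucleotide string into codons
#' @param seq nucleotide string whose length is a multiple of 3
#' @return character vector of codons
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

# All 9 single-base variants of a codon, with the position and target base
single_base_variants <- function(codon) {
  cached <- get0(codon, envir = .codon_env$variants)
  if (!is.null(cached)) return(cached)
  chars <- strsplit(codon, "")[[1]]
  pos <- rep(1:3, each = 3)
  from <- chars[pos]
  to <- unlist(lapply(1:3, function(p) setdiff(NUCS, chars[p])),
               use.names = FALSE)
  variant <- vapply(seq_along(pos), function(k) {
    mutated <- chars
    mutated[pos[k]] <- to[k]
    paste(mutated, collapse = "")
  }, "")
  out <- list(pos = pos, from = from, to = to, codon = variant)
  assign(codon, out, envir = .codon_env$variants)
  out
}

# character matrix (alleles x sites) from a vector of equal-length strings
seq_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  do.call(rbind, strsplit(seqs, ""))
}

collapse_seq <- function(mat) apply(mat, 1, paste, collapse = "")
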