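# Fixtures built in code: small locus tables with known structure.

# a coding locus: 4 codons CDS (12 bp) + 6 bp intergenic tail
toy_ref <- function() paste0("ATGCTTACCGGA", "TTTGGC")

toy_table <- function(sequences, counts, ref_b = toy_ref(), ref_a = NULL,
                      cds = TRUE) {
  ci <- if (cds) data.frame(start = 0L, end = 12L, strand = "+", frame = 0L,
                            hypothetical = 0L) else NULL
  tb <- locus_table("toy", sequences, counts, ref_b = ref_b, ref_a = ref_a,
                    coding_intervals = ci)
  if (cds) tb$designated_cds <- 1L
  tb
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# write a table set to temp FASTA/TSV files, returning the paths
write_fixture_files <- function(tables) {
  paths <- list(
    fasta = tempfile(fileext = ".fasta"),
    counts = tempfile(fileext = ".tsv"),
    ann = tempfile(fileext = ".tsv"),
    refs = tempfile(fileext = ".fasta"))
  write_locus_tables(tables, paths$fasta, paths$counts, paths$ann, paths$refs)
  paths
}

# brute-force complete-linkage clustering oracle (O(n^3))
brute_complete_linkage <- function(dm, threshold) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL; best_d <- Inf
    if (length(clusters) == 1) break
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  assign
}
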