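# Per-locus allele tables: data model, I/O, filtering, codon-aware alignment.
#
# Allele sequences are stored projected onto the reference coordinate frame of
# their locus: every sequence has length L, deletions relative to the
# reference appear as '-', and insertions are dropped (columns exist only
# where the reference carries a base). This mirrors reference-anchored
# analyses in which the coding frame of the reference genome is enforced.

#' Construct a per-locus allele table
#'
#' @param locus_id locus identifier
#' @param sequences character vector of aligned allele sequences (A/C/G/T/-),
#'   all the same length
#' @param read_counts non-negative integer read counts, one per sequence
#' @param ref_b,ref_a optional reference homolog sequences (same length)
#' @param coding_intervals optional data.frame with columns start, end (0-based
#'   half-open), strand ("+"/"-"), frame (0-2), hypothetical (0/1)
#' @param allele_ids optional ids; generated as "<locus_id>|<i>" when missing
#' @return object of class `locus_table` with alleles ordered by descending
#'   read count, ties broken by lexicographically smallest sequence
#' @export
locus_table <- function(locus_id, sequences, read_counts,
                        ref_b = NULL, ref_a = NULL,
                        coding_intervals = NULL, allele_ids = NULL) {
  stopifnot(length(sequences) == length(read_counts))
  if (length(sequences) > 0) {
    bad <- regexpr("[^ACGT-]", sequences)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1]
      stop(sprintf("locus %s: non-ACGT- character at position %d of allele %d",
                   locus_id, bad[i], i))
    }
    L <- unique(nchar(sequences))
    if (length(L) != 1)
      stop(sprintf("locus %s: allele sequences have unequal lengths", locus_id))
  } else {
    L <- if (!is.null(ref_b)) nchar(ref_b) else 0L
  }
  read_counts <- as.integer(read_counts)
  stopifnot(all(read_counts >= 0))
  if (is.null(allele_ids)) allele_ids <- paste0(locus_id, "|", seq_along(sequences))
  ord <- order(-read_counts, sequences)
  alleles <- data.frame(allele_id = allele_ids[ord],
                        sequence = sequences[ord],
                        read_count = read_counts[ord],
                        stringsAsFactors = FALSE)
  depth <- sum(alleles$read_count)
  alleles$frequency <- if (depth > 0) alleles$read_count / depth else
    rep(NA_real_, nrow(alleles))
  if (!is.null(coding_intervals)) {
    coding_intervals <- as.data.frame(coding_intervals)
    stopifnot(all(c("start", "end") %in% names(coding_intervals)))
    if (is.null(coding_intervals$strand)) coding_intervals$strand <- "+"
    if (is.null(coding_intervals$frame)) coding_intervals$frame <- 0L
    if (is.null(coding_intervals$hypothetical)) coding_intervals$hypothetical <- 0L
    stopifnot(all(coding_intervals$start >= 0),
              all(coding_intervals$end <= L),
              all(coding_intervals$start < coding_intervals$end))
    ci <- coding_intervals[order(coding_intervals$start), , drop = FALSE]
    if (nrow(ci) > 1 && any(ci$start[-1] < ci$end[-nrow(ci)]))
      stop(sprintf("locus %s: overlapping coding intervals", locus_id))
  }
  structure(list(locus_id = locus_id, alleles = alleles, depth = depth,
                 ref_b = ref_b, ref_a = ref_a,
                 coding_intervals = coding_intervals,
                 designated_cds = NA_integer_, L = as.integer(L)),
            class = "locus_table")
}

#' @export
print.locus_table <- function(x, ...) {
  cat(sprintf("locus_table %s: %d alleles, depth %d, L = %d\n",
              x$locus_id, nrow(x$alleles), x$depth, x$L))
  if (!is.null(x$coding_intervals))
    cat(sprintf("  %d coding interval(s); designated: %s\n",
                nrow(x$coding_intervals),
                ifelse(is.na(x$designated_cds), "none", x$designated_cds)))
  invisible(x)
}

#' Read per-locus allele tables from FASTA + TSV files
#'
#' @param allele_fasta_path FASTA of aligned allele sequences, ids
#'   "locusID|alleleIndex"
#' @param counts_tsv_path TSV with columns locus_id, allele_id, reads
#' @param annotation_path optional TSV with columns locus_id, start, end,
#'   strand, frame, hypothetical (0-based half-open coordinates)
#' @param refs_fasta_path optional FASTA of reference homologs with ids
#'   "locusID|ref_b" / "locusID|ref_a"
#' @return list of `locus_table`, frequencies computed, deterministic
#'   ordering (descending read count then lexicographic sequence)
#' @export
read_locus_tables <- function(allele_fasta_path, counts_tsv_path,
                              annotation_path = NULL, refs_fasta_path = NULL) {
  seqs <- Biostrings::readBStringSet(allele_fasta_path)
  if (length(seqs) == 0) {
    warning("empty allele FASTA: no locus tables read")
    return(list())
  }
  ids <- names(seqs)
  counts <- utils::read.table(counts_tsv_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "allele_id", "reads") %in% names(counts)))
  missing_in_fasta <- setdiff(counts$allele_id, ids)
  if (length(missing_in_fasta) > 0)
    stop("count rows with ids absent from FASTA: ",
         paste(missing_in_fasta, collapse = ", "))
  cnt <- stats::setNames(counts$reads, counts$allele_id)
  if (any(!(ids %in% names(cnt))))
    stop("missing count for id(s): ",
         paste(setdiff(ids, names(cnt)), collapse = ", "))
  locus_of <- sub("\\|[^|]*$", "", ids)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  refs <- NULL
  if (!is.null(refs_fasta_path))
    refs <- Biostrings::readBStringSet(refs_fasta_path)
  out <- list()
  for (loc in unique(locus_of)) {
    sel <- locus_of == loc
    ref_b <- ref_a <- NULL
    if (!is.null(refs)) {
      if (paste0(loc, "|ref_b") %in% names(refs))
        ref_b <- as.character(refs[[paste0(loc, "|ref_b")]])
      if (paste0(loc, "|ref_a") %in% names(refs))
        ref_a <- as.character(refs[[paste0(loc, "|ref_a")]])
    }
    ci <- NULL
    if (!is.null(ann) && any(ann$locus_id == loc))
      ci <- ann[ann$locus_id == loc,
                c("start", "end", "strand", "frame", "hypothetical")]
    out[[loc]] <- locus_table(loc, as.character(seqs[sel]),
                              as.integer(cnt[ids[sel]]),
                              ref_b = ref_b, ref_a = ref_a,
                              coding_intervals = ci, allele_ids = ids[sel])
  }
  out
}

#' Write locus tables to FASTA + TSV (inverse of [read_locus_tables])
#'
#' @param tables list of `locus_table`
#' @param allele_fasta_path,counts_tsv_path,annotation_path,refs_fasta_path
#'   output paths (annotation/refs written only when any table carries them)
#' @return invisibly, the paths written
#' @export
write_locus_tables <- function(tables, allele_fasta_path, counts_tsv_path,
                               annotation_path = NULL, refs_fasta_path = NULL) {
  all_seq <- character(0); all_id <- character(0)
  counts <- list(); ann <- list(); refs <- character(0)
  for (tb in tables) {
    all_seq <- c(all_seq, tb$alleles$sequence)
    all_id <- c(all_id, tb$alleles$allele_id)
    counts[[tb$locus_id]] <- data.frame(locus_id = tb$locus_id,
                                        allele_id = tb$alleles$allele_id,
                                        reads = tb$alleles$read_count,
                                        stringsAsFactors = FALSE)
    if (!is.null(tb$coding_intervals)) {
      ci <- tb$coding_intervals
      ci$locus_id <- tb$locus_id
      ann[[tb$locus_id]] <- ci[, c("locus_id", "start", "end", "strand",
                                   "frame", "hypothetical")]
    }
    if (!is.null(tb$ref_b)) refs[paste0(tb$locus_id, "|ref_b")] <- tb$ref_b
    if (!is.null(tb$ref_a)) refs[paste0(tb$locus_id, "|ref_a")] <- tb$ref_a
  }
  ss <- Biostrings::BStringSet(all_seq)
  names(ss) <- all_id
  Biostrings::writeXStringSet(ss, allele_fasta_path)
  utils::write.table(do.call(rbind, counts), counts_tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path) && length(ann) > 0)
    utils::write.table(do.call(rbind, ann), annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(refs_fasta_path) && length(refs) > 0) {
    rs <- Biostrings::BStringSet(unname(refs))
    names(rs) <- names(refs)
    Biostrings::writeXStringSet(rs, refs_fasta_path)
  }
  invisible(c(allele_fasta_path, counts_tsv_path))
}

#' Keep only deeply read loci
#'
#' @param tables list of `locus_table`
#' @param min_reads minimum total depth (>= 1); the default reproduces the
#'   >= 300 read screen used to define deeply read loci
#' @return filtered list, original order preserved
#' @export
filter_deep_loci <- function(tables, min_reads = 300) {
  stopifnot(min_reads >= 1)
  Filter(function(tb) tb$depth >= min_reads, tables)
}

#' Keep loci with a usable designated coding sequence
#'
#' Designates, per locus, the longest coding interval (ties broken by the
#' leftmost). The locus is dropped if that interval is shorter than `min_aa`
#' codons or flagged hypothetical, or if the locus has no coding interval.
#'
#' @param tables list of `locus_table`
#' @param min_aa minimum designated-CDS length in amino acids
#' @return filtered list with `designated_cds` set on each survivor
#' @export
filter_coding_loci <- function(tables, min_aa = 50) {
  out <- list()
  for (tb in tables) {
    ci <- tb$coding_intervals
    if (is.null(ci) || nrow(ci) == 0) next
    len <- ci$end - ci$start
    best <- which(len == max(len))
    best <- best[which.min(ci$start[best])]
    n_codons <- (ci$end[best] - ci$start[best] - ci$frame[best]) %/% 3
    if (ci$hypothetical[best] != 0 || n_codons < min_aa) next
    tb$designated_cds <- best
    out[[tb$locus_id]] <- tb
  }
  out
}

designated_interval <- function(table) {
  if (is.na(table$designated_cds))
    stop(sprintf("locus %s: no designated coding interval; run filter_coding_loci",
                 table$locus_id))
  table$coding_intervals[table$designated_cds, , drop = FALSE]
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-")
  rev(unname(comp[chars]))
}

# Extract the designated-CDS portion of a sequence, strand/frame resolved,
# trimmed to whole codons. Returns a character vector of bases.
cds_chars <- function(seq, interval) {
  chars <- strsplit(seq, "")[[1]][(interval$start + 1):interval$end]
  if (interval$strand == "-") chars <- revcomp_chars(chars)
  if (interval$frame > 0) chars <- chars[-(1:interval$frame)]
  extra <- length(chars) %% 3
  if (extra > 0) chars <- chars[1:(length(chars) - extra)]
  chars
}

#' Codon-aware alignment of an allele to its locus reference
#'
#' Pairs reference and allele codons over the designated coding interval;
#' any codon in which the allele carries an indel is gapped out completely
#' (both codon slots set to the NA gap sentinel), and the remaining codons
#' stay in the reference reading frame.
#'
#' @param allele allele sequence (string) or row index into `table$alleles`
#' @param table a `locus_table` with a designated coding interval and a
#'   reference homolog (ref_b preferred, ref_a fallback)
#' @return object of class `codon_alignment`: list with `ref_codons`,
#'   `allele_codons` (NA = gap sentinel) and `n_codons`
#' @export
codon_align <- function(allele, table) {
  if (is.numeric(allele)) allele <- table$alleles$sequence[allele]
  interval <- designated_interval(table)
  ref <- if (!is.null(table$ref_b)) table$ref_b else table$ref_a
  if (is.null(ref)) stop("codon_align requires a reference homolog")
  rc <- cds_chars(ref, interval)
  ac <- cds_chars(allele, interval)
  n <- length(rc) %/% 3
  ref_codons <- allele_codons <- character(n)
  for (k in seq_len(n)) {
    idx <- (3 * k - 2):(3 * k)
    ref_codons[k] <- paste(rc[idx], collapse = "")
    allele_codons[k] <- paste(ac[idx], collapse = "")
  }
  gapped <- grepl("-", allele_codons) | grepl("-", ref_codons)
  ref_codons[gapped] <- NA_character_
  allele_codons[gapped] <- NA_character_
  structure(list(ref_codons = ref_codons, allele_codons = allele_codons,
                 n_codons = n), class = "codon_alignment")
}

pair_identity <- function(a, b) {
  am <- strsplit(a, "")[[1]]; bm <- strsplit(b, "")[[1]]
  ok <- am != "-" & bm != "-"
  if (!any(ok)) return(0)
  mean(am[ok] == bm[ok])
}

#' Screen alleles that are non-homologous to both references
#'
#' Flags alleles whose gap-free column identity to both reference homologs
#' falls below `min_identity`, removes them, and renormalizes frequencies.
#'
#' @param tables list of `locus_table`, each with ref_b and/or ref_a
#' @param min_identity identity threshold in [0,1]
#' @return list with `kept` (screened tables) and `flagged` (data.frame of
#'   removed alleles with identities)
#' @export
screen_nonhomologous <- function(tables, min_identity = 0.5) {
  flagged <- list()
  kept <- list()
  for (tb in tables) {
    if (is.null(tb$ref_b) && is.null(tb$ref_a))
      stop(sprintf("locus %s: no reference homolog for homology screen",
                   tb$locus_id))
    id_b <- if (!is.null(tb$ref_b))
      vapply(tb$alleles$sequence, pair_identity, 0, b = tb$ref_b) else
      rep(-Inf, nrow(tb$alleles))
    id_a <- if (!is.null(tb$ref_a))
      vapply(tb$alleles$sequence, pair_identity, 0, b = tb$ref_a) else
      rep(-Inf, nrow(tb$alleles))
    bad <- pmax(id_b, id_a) < min_identity
    if (any(bad)) {
      flagged[[tb$locus_id]] <- data.frame(
        locus_id = tb$locus_id, allele_id = tb$alleles$allele_id[bad],
        identity_ref_b = ifelse(is.finite(id_b[bad]), id_b[bad], NA),
        identity_ref_a = ifelse(is.finite(id_a[bad]), id_a[bad], NA),
        stringsAsFactors = FALSE)
      tb2 <- locus_table(tb$locus_id, tb$alleles$sequence[!bad],
                         tb$alleles$read_count[!bad],
                         ref_b = tb$ref_b, ref_a = tb$ref_a,
                         coding_intervals = tb$coding_intervals,
                         allele_ids = tb$alleles$allele_id[!bad])
      tb2$designated_cds <- tb$designated_cds
      kept[[tb$locus_id]] <- tb2
    } else {
      kept[[tb$locus_id]] <- tb
    }
  }
  flagged <- if (length(flagged) > 0) do.call(rbind, flagged) else
    data.frame(locus_id = character(0), allele_id = character(0),
               identity_ref_b = numeric(0), identity_ref_a = numeric(0))
  rownames(flagged) <- NULL
  list(kept = kept, flagged = flagged)
}
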