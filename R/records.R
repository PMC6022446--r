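#' Build a contig table
#'
#' Contigs are kept as a plain data frame: one row per contig with its
#' identifier, sequence, length and topology. Topology records whether the
#' underlying replicon is known to be circular (e.g. inovirus or circovirus
#' genomes), which matters both for read simulation (fragments may span the
#' junction) and for bias summaries that stratify circular vs linear contigs.
#'
#' @param id character vector of unique contig identifiers.
#' @param seq character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @param topology one of `"linear"`, `"circular"`, `"unknown"` (recycled).
#' @return data frame with columns `id`, `seq`, `length_nt`, `topology`.
#' @export
contig_set <- function(id, seq, topology = "unknown") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (anyDuplicated(id)) stop("contig ids must be unique")
  if (any(!nzchar(seq))) stop("contig sequences must be nonempty")
  if (any(grepl("[^ACGTN]", seq))) stop("contig sequences must be over {A,C,G,T,N}")
  topology <- rep_len(match.arg(topology, c("linear", "circular", "unknown"),
                                several.ok = TRUE), length(id))
  data.frame(id = id, seq = seq, length_nt = nchar(seq), topology = topology,
             stringsAsFactors = FALSE)
}

#' Build a read table
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual optional per-base quality strings (Sanger Phred+33), same
#'   length as `seq` elementwise, or `NA`.
#' @param mate `1`, `2` or `"none"` (recycled).
#' @param sample source sample label (recycled).
#' @return data frame with columns `id`, `seq`, `qual`, `mate`, `sample`.
#' @export
read_set <- function(id, seq, qual = NA_character_, mate = "none",
                     sample = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  qual <- rep_len(as.character(qual), length(id))
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) stop("qual must be absent or the same length as seq")
  data.frame(id = id, seq = seq, qual = qual,
             mate = rep_len(as.character(mate), length(id)),
             sample = rep_len(as.character(sample), length(id)),
             stringsAsFactors = FALSE)
}

#' GC content of DNA sequences
#'
#' Fraction of called bases (`A`/`C`/`G`/`T`) that are `G` or `C`. `N` bases
#' are excluded from both numerator and denominator; a sequence with no
#' called bases yields `NA`.
#'
#' @param seq character vector of DNA sequences.
#' @param as_pct return percent (0-100) instead of a fraction (0-1).
#' @return numeric vector in `[0, 1]` (or `[0, 100]`), `NA` where all-N.
#' @export
gc_content <- function(seq, as_pct = FALSE) {
  seq <- toupper(as.character(seq))
  if (length(seq) == 0L || any(!nzchar(seq) | is.na(seq)))
    stop("sequences must be nonempty")
  counts <- gc_counts_cpp(seq)  # matrix: rows = (gc, acgt)
  out <- ifelse(counts[2L, ] > 0, counts[1L, ] / counts[2L, ], NA_real_)
  if (as_pct) 100 * out else out
}

#' Reverse complement
#' @param seq character vector of DNA sequences (IUPAC handled for ACGTN).
#' @return character vector.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Subsample reads without replacement
#'
#' Uniform sampling without replacement, deterministic for a fixed input
#' order, `n` and `seed`. Used to put all viromes on an equal footing before
#' cross-sample comparisons (the study analyses fixed-size subsamples per
#' virome).
#'
#' @param reads read table (see [read_set()]).
#' @param n number of reads to keep; must not exceed `nrow(reads)`.
#' @param seed integer seed.
#' @return read table with exactly `n` rows.
#' @export
subsample_reads <- function(reads, n, seed) {
  if (n > nrow(reads)) stop("n exceeds the number of available reads")
  idx <- with_seed(seed, sample.int(nrow(reads), n, replace = FALSE))
  reads[idx, , drop = FALSE]
}

#' Read and write FASTA contigs
#'
#' Thin wrappers over Biostrings. Topology is not encoded in FASTA; reading
#' returns `"unknown"` unless the description carries a `topology=circular`
#' tag, which writing emits for circular contigs.
#'
#' @param path file path.
#' @return [read_fasta_contigs()]: a contig table.
#' @export
read_fasta_contigs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  topo <- ifelse(grepl("topology=circular", nm), "circular",
                 ifelse(grepl("topology=linear", nm), "linear", "unknown"))
  contig_set(sub("\\s.*$", "", nm), as.character(ss), topo)
}

#' @rdname read_fasta_contigs
#' @param contigs contig table.
#' @export
write_fasta_contigs <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$seq)
  tag <- ifelse(contigs$topology %in% c("circular", "linear"),
                paste0(" topology=", contigs$topology), "")
  names(ss) <- paste0(contigs$id, tag)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write FASTQ reads
#'
#' @param path file path.
#' @param sample sample label to attach on reading.
#' @return [read_fastq_reads()]: a read table.
#' @export
read_fastq_reads <- function(path, sample = NA_character_) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  read_set(sub("\\s.*$", "", names(ss)), as.character(ss), qual, sample = sample)
}

#' @rdname read_fastq_reads
#' @param reads read table.
#' @export
write_fastq_reads <- function(reads, path) {
  qual <- reads$qual
  qual[is.na(qual)] <- vapply(nchar(reads$seq)[is.na(qual)],
                              function(n) strrep("I", n), "")
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
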