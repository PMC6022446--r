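#' Map reads to contigs under a strict full-length identity contract
#'
#' Seed-and-extend, end-to-end (ungapped) placement of each read on both
#' strands of the contig set. A read is reported once, at its single best
#' placement, and only when the identity over the *full read length* is
#' strictly greater than `min_identity`; this mirrors strict short-read
#' alignment settings that recruit each read at most once and reject
#' placements below ~96% identity. Ties are broken by fewest mismatches,
#' then lexicographically smallest contig id, then smallest start.
#'
#' @param reads read table ([read_set()]).
#' @param contigs contig table ([contig_set()]).
#' @param min_identity retain placements with identity strictly above this.
#' @param seed_k seed k-mer length.
#' @param seed_step stride between seeds along the read.
#' @return alignment data frame with columns `read_id`, `contig_id`,
#'   `start` (0-based), `end` (exclusive), `strand`, `mismatches`,
#'   `indels`, `identity`.
#' @export
map_reads <- function(reads, contigs, min_identity = 0.96, seed_k = 15,
                      seed_step = 8) {
  if (nrow(contigs) == 0L) stop("contig set must be nonempty")
  map_reads_cpp(reads$id, reads$seq, contigs$id, contigs$seq,
                min_identity = min_identity, seed_k = seed_k,
                seed_step = seed_step)
}

#' Write alignments as SAM text
#'
#' Minimal SAM emitter used for interchange with standard tooling: one
#' `@SQ` header per contig and one primary record per alignment, with the
#' read sequence (reverse-complemented for `-` strand records, per SAM
#' convention) and an `NM` tag carrying mismatches + indels.
#'
#' @param alignments alignment data frame (see [map_reads()]).
#' @param contigs contig table.
#' @param reads read table supplying sequences.
#' @param path output file path.
#' @export
write_sam <- function(alignments, contigs, reads, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, contigs$length_nt))
  seqs <- setNames(reads$seq, reads$id)
  out <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    s <- seqs[[a$read_id]]
    flag <- if (a$strand == "-") 16L else 0L
    if (a$strand == "-") s <- revcomp(s)
    out[i] <- paste(a$read_id, flag, a$contig_id, a$start + 1L, 255L,
                    paste0(nchar(s), "M"), "*", 0L, 0L, s, "*",
                    paste0("NM:i:", a$mismatches + a$indels), sep = "\t")
  }
  writeLines(c(hdr, out), path)
  invisible(path)
}

#' Ingest SAM alignments under the strict identity contract
#'
#' Parses SAM text, drops unmapped, secondary and supplementary records, and
#' keeps one record per primary alignment whose full-read identity is
#' strictly greater than `min_identity`. Identity is computed over the total
#' read length: soft-clipped bases count as non-matching, mismatches come
#' from the `NM` tag minus inserted/deleted bases (CIGAR `I`/`D`).
#'
#' @param path SAM file path, or a character vector of SAM lines via `lines`.
#' @param lines optional character vector of SAM lines (overrides `path`).
#' @param min_identity retain records with identity strictly above this.
#' @return alignment data frame (see [map_reads()]).
#' @export
ingest_alignments <- function(path = NULL, lines = NULL, min_identity = 0.96) {
  if (is.null(lines)) lines <- readLines(path)
  keep_i <- which(!startsWith(lines, "@"))
  res <- vector("list", length(keep_i))
  for (k in seq_along(keep_i)) {
    ln <- keep_i[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop(sprintf("malformed SAM line %d: fewer than 11 fields", ln))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) stop(sprintf("malformed SAM line %d: bad FLAG/POS", ln))
    if (bitwAnd(flag, 0x4) != 0L) next          # unmapped
    if (bitwAnd(flag, 0x100) != 0L) next        # secondary
    if (bitwAnd(flag, 0x800) != 0L) next        # supplementary
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    if (length(ops) == 0L) stop(sprintf("malformed SAM line %d: bad CIGAR", ln))
    n_op <- as.integer(sub("[MIDNSHP=X]", "", ops))
    t_op <- sub("\\d+", "", ops)
    m_len <- sum(n_op[t_op %in% c("M", "=", "X")])
    i_len <- sum(n_op[t_op == "I"])
    d_len <- sum(n_op[t_op == "D"])
    s_len <- sum(n_op[t_op == "S"])
    read_len <- m_len + i_len + s_len
    nm_f <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    nm <- if (length(nm_f)) as.integer(sub("NM:i:", "", nm_f[1])) else NA_integer_
    if (is.na(nm)) stop(sprintf("malformed SAM line %d: missing NM tag", ln))
    mm <- nm - i_len - d_len
    identity <- (m_len - mm) / read_len
    if (!(identity > min_identity)) next
    res[[k]] <- data.frame(
      read_id = f[1], contig_id = f[3], start = pos - 1L,
      end = pos - 1L + m_len + d_len,
      strand = if (bitwAnd(flag, 0x10) != 0L) "-" else "+",
      mismatches = mm, indels = i_len + d_len, identity = identity,
      stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L)
    return(data.frame(read_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), indels = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
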