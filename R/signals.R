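#' Linguistic complexity track along a contig
#'
#' Trifonov-style linguistic complexity in sliding windows: the product
#' over word sizes `k = 1..kmax` of the number of distinct k-mers observed
#' in the window divided by the maximum possible, `min(4^k, W - k + 1)`.
#' A window reaches 1 only when every word-size level is at capacity;
#' repeats and homopolymers drive it towards 0. The final partial window is
#' dropped.
#'
#' @param contig single-row contig table (or a bare sequence string).
#' @param window_nt window width.
#' @param step_nt step between window starts.
#' @param kmax largest word size in the product.
#' @return data frame `start` (0-based), `end` (exclusive), `complexity`.
#' @export
linguistic_complexity <- function(contig, window_nt = 50, step_nt = 20,
                                  kmax = 7) {
  seq <- if (is.data.frame(contig)) contig$seq[1] else contig
  L <- nchar(seq)
  if (L < window_nt) stop("contig shorter than the window")
  starts <- seq.int(1L, L - window_nt + 1L, by = step_nt)
  cx <- vapply(starts, function(s) {
    w <- substr(seq, s, s + window_nt - 1L)
    window_complexity(w, kmax)
  }, 0)
  data.frame(start = starts - 1L, end = starts + window_nt - 1L,
             complexity = cx)
}

# Complexity of a single window (product over k of vocabulary usage).
window_complexity <- function(w, kmax) {
  W <- nchar(w)
  prod(vapply(seq_len(min(kmax, W)), function(k) {
    n_pos <- W - k + 1L
    v <- length(unique(substring(w, 1:n_pos, k:W)))
    v / min(4^k, n_pos)
  }, 0))
}

#' Primer specification for site scanning and trimming
#'
#' SISPA primers carry a constant 5' part and a degenerate 3' tail (IUPAC
#' ambiguity codes, typically `N` runs). Site scanning uses the 8 substrings
#' of length 8 taken from the last 15 nt of the constant part; trimming
#' uses three overlapping 15-nt substrings of the constant part.
#'
#' @param name primer label.
#' @param seq primer sequence (constant part first, degenerate tail after).
#' @return list of class `primer_spec`: `name`, `seq`, `constant`,
#'   `scan_words` (8 strings of 8 nt), `trim_words` (3 strings of 15 nt).
#' @export
primer_spec <- function(name, seq) {
  seq <- toupper(seq)
  constant <- sub("[^ACGT].*$", "", seq)
  if (nchar(constant) < 15)
    stop("primer constant part must be at least 15 nt of concrete bases")
  last15 <- substr(constant, nchar(constant) - 14L, nchar(constant))
  scan_words <- substring(last15, 1:8, 8:15)
  lc <- nchar(constant)
  offs <- unique(c(1L, (lc - 15L) %/% 2L + 1L, lc - 14L))
  trim_words <- substring(constant, offs, offs + 14L)
  structure(list(name = name, seq = seq, constant = constant,
                 scan_words = scan_words, trim_words = trim_words),
            class = "primer_spec")
}

#' Scan a contig for primer-derived words
#'
#' Exact matches of any of the primer's 8-mer scan words on either strand,
#' reported on forward coordinates. These mark potential preferential
#' annealing sites of the primer's constant part.
#'
#' @param contig single-row contig table (or sequence string).
#' @param primer [primer_spec()].
#' @return data frame `position` (0-based match start), `strand`, `word`.
#' @export
scan_primer_sites <- function(contig, primer) {
  seq <- if (is.data.frame(contig)) contig$seq[1] else contig
  hits <- lapply(primer$scan_words, function(w) {
    fwd <- gregexpr(w, seq, fixed = TRUE)[[1]]
    rcw <- revcomp(w)
    rev <- gregexpr(rcw, seq, fixed = TRUE)[[1]]
    rbind(
      if (fwd[1] > 0) data.frame(position = as.integer(fwd) - 1L,
                                 strand = "+", word = w,
                                 stringsAsFactors = FALSE),
      if (rev[1] > 0) data.frame(position = as.integer(rev) - 1L,
                                 strand = "-", word = w,
                                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(position = integer(), strand = character(),
                      word = character(), stringsAsFactors = FALSE))
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}

#' Trim primer sequence from read starts
#'
#' The three overlapping 15-nt substrings of the primer's constant part are
#' searched within each read's first `search_window_nt` bases allowing at
#' most `max_errors` mismatches; on any hit, bases from the read start
#' through the furthest-right match end are removed. Reads trimmed by more
#' than 35 bases carry a primer concatemer (primer-dimer); see
#' [primer_dimer_windows()].
#'
#' @param reads read table.
#' @param primer [primer_spec()].
#' @param max_errors mismatches tolerated per 15-mer.
#' @param search_window_nt how far into the read to search.
#' @return list: `reads` (trimmed read table) and `bases_removed` (named
#'   integer vector per read id).
#' @export
trim_primer <- function(reads, primer, max_errors = 1, search_window_nt = 50) {
  removed <- trim_scan_cpp(reads$seq, primer$trim_words,
                           window = search_window_nt, max_err = max_errors)
  out <- reads
  out$seq <- substring(reads$seq, removed + 1L)
  out$qual <- ifelse(is.na(reads$qual), reads$qual,
                     substring(reads$qual, removed + 1L))
  list(reads = out, bases_removed = setNames(as.integer(removed), reads$id))
}

#' Percentage of primer-dimer reads along a contig
#'
#' A read is dimer-flagged when strictly more than `dimer_threshold_bp`
#' bases were trimmed from its 5' end. Per sliding window, the percentage
#' of overlapping aligned reads that are dimer-flagged is reported; windows
#' with no overlapping reads are `NA`, not 0.
#'
#' @param alignments alignment data frame for one contig.
#' @param bases_removed named vector from [trim_primer()] covering all
#'   aligned reads.
#' @param contig single-row contig table.
#' @param window_nt,step_nt window geometry.
#' @param dimer_threshold_bp strict trimming threshold.
#' @return data frame `start` (0-based), `end` (exclusive),
#'   `pct_dimer_reads`.
#' @export
primer_dimer_windows <- function(alignments, bases_removed, contig,
                                 window_nt = 50, step_nt = 20,
                                 dimer_threshold_bp = 35) {
  a <- alignments[alignments$contig_id == contig$id, , drop = FALSE]
  if (any(!a$read_id %in% names(bases_removed)))
    stop("bases_removed must cover all aligned reads")
  flag <- bases_removed[a$read_id] > dimer_threshold_bp
  L <- contig$length_nt
  starts <- seq.int(0L, L - window_nt, by = step_nt)
  res <- vapply(starts, function(s) {
    ov <- a$start < s + window_nt & a$end > s
    n <- sum(ov)
    if (n == 0L) NA_real_ else 100 * sum(flag[ov]) / n
  }, 0)
  data.frame(start = starts, end = starts + window_nt, pct_dimer_reads = res)
}

#' Detect contig circularity from junction-spanning reads
#'
#' A read supports circularity when it splits into a prefix arm aligning up
#' to the contig's 3' terminus and a suffix arm aligning from the 5'
#' terminus, in consistent order and orientation, each arm at least
#' `min_overlap_nt` read bases with at most `max_mismatches` mismatches and
#' `max_indels` indels (unit-cost edit alignment against the terminal
#' `end_segment_nt` of the contig). Both read orientations are tried.
#'
#' @param contig single-row contig table.
#' @param reads read table.
#' @param min_overlap_nt minimum arm length (per arm).
#' @param max_mismatches,max_indels per-arm alignment tolerances.
#' @param end_segment_nt terminal segment length searched on each side.
#' @param min_support junction reads required to call the contig circular.
#' @return list of class `circularity_call`: `contig_id`, `is_circular`,
#'   `supporting_reads`, `junction_offsets` (split positions within
#'   supporting reads), `read_ids`.
#' @export
detect_circularity <- function(contig, reads, min_overlap_nt = 60,
                               max_mismatches = 3, max_indels = 2,
                               end_segment_nt = 1000, min_support = 1) {
  if (contig$length_nt < 2 * min_overlap_nt)
    stop("contig shorter than twice the minimum overlap")
  sup <- circ_support_cpp(reads$seq, contig$seq,
                         min_overlap = min_overlap_nt,
                         max_mm = max_mismatches, max_ind = max_indels,
                         end_segment = end_segment_nt)
  hit <- sup$supports == 1L
  structure(list(contig_id = contig$id,
                 is_circular = sum(hit) >= min_support,
                 supporting_reads = sum(hit),
                 junction_offsets = sup$split[hit],
                 read_ids = reads$id[hit]),
            class = "circularity_call")
}

#' Annotate high-coverage peaks with candidate sequence signals
#'
#' Each peak is labelled `primer_specific` when scan hits of exactly one
#' primer fall within the peak extended by `flank_nt`, `low_complexity`
#' when any overlapped complexity window lies below the contig-wide
#' `low_complexity_quantile`, `both`, or `neither`.
#'
#' @param peaks data frame from [detect_high_coverage_peaks()].
#' @param complexity data frame from [linguistic_complexity()].
#' @param primer_hits named list of scan-hit data frames, one per primer
#'   ([scan_primer_sites()]).
#' @param low_complexity_quantile quantile of the contig's window
#'   complexities under which a window counts as low-complexity.
#' @param flank_nt symmetric extension of the peak when matching hits.
#' @return list: `annotations` (peaks plus `category`) and `counts`
#'   (named vector over the four categories).
#' @export
associate_peaks_with_signals <- function(peaks, complexity, primer_hits,
                                         low_complexity_quantile = 0.2,
                                         flank_nt = 100) {
  thr <- quantile(complexity$complexity, low_complexity_quantile, names = FALSE)
  category <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lo <- peaks$start[i] - flank_nt
    hi <- peaks$end[i] + flank_nt
    n_primers <- sum(vapply(primer_hits, function(h)
      any(h$position >= lo & h$position < hi), TRUE))
    primer_specific <- n_primers == 1L
    ov <- complexity$start < peaks$end[i] & complexity$end > peaks$start[i]
    low_cx <- any(complexity$complexity[ov] < thr)
    category[i] <- if (primer_specific && low_cx) "both"
      else if (primer_specific) "primer_specific"
      else if (low_cx) "low_complexity"
      else "neither"
  }
  ann <- peaks
  ann$category <- category
  counts <- table(factor(category, levels = c("primer_specific",
                                              "low_complexity", "both",
                                              "neither")))
  list(annotations = ann, counts = setNames(as.integer(counts), names(counts)))
}
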