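#' Contig abundance matrix in RPKM
#'
#' Each retained alignment increments its contig's count once (reads are
#' already single-placement under the strict mapping contract), and
#' `rpkm = count / (contig_kb * library_millions)`. The library size is the
#' number of reads submitted to mapping for that sample; when viromes are
#' compared on fixed-size subsamples this equals the subsample size.
#'
#' @param alignments named list of alignment data frames, one per sample.
#' @param contigs contig table.
#' @param library_sizes named integer vector of per-sample library sizes;
#'   a single unnamed value is recycled.
#' @return list of class `abundance_matrix`: `rpkm` and `counts`
#'   (contigs x samples matrices), `library_sizes`, `contig_length`.
#' @export
compute_rpkm <- function(alignments, contigs, library_sizes) {
  samples <- names(alignments)
  if (is.null(samples)) stop("alignments must be a named list (one per sample)")
  if (length(library_sizes) == 1L && is.null(names(library_sizes)))
    library_sizes <- setNames(rep(library_sizes, length(samples)), samples)
  if (any(library_sizes < 1)) stop("library sizes must be >= 1")
  counts <- matrix(0L, nrow(contigs), length(samples),
                   dimnames = list(contigs$id, samples))
  for (s in samples) {
    a <- alignments[[s]]
    if (nrow(a) == 0L) next
    unknown <- setdiff(unique(a$contig_id), contigs$id)
    if (length(unknown))
      stop(sprintf("alignment to unknown contig: %s", unknown[1]))
    tab <- table(a$contig_id)
    counts[names(tab), s] <- as.integer(tab)
  }
  len_kb <- contigs$length_nt / 1000
  lib_m <- library_sizes[samples] / 1e6
  rpkm <- sweep(counts / len_kb, 2, lib_m, "/")
  structure(list(rpkm = rpkm, counts = counts,
                 library_sizes = library_sizes[samples],
                 contig_length = setNames(contigs$length_nt, contigs$id)),
            class = "abundance_matrix")
}

# Accept either an abundance_matrix or a bare rpkm matrix.
rpkm_of <- function(x) if (inherits(x, "abundance_matrix")) x$rpkm else as.matrix(x)

#' Per-contig fold changes against a reference sample
#'
#' `fold_change = rpkm(sample) / rpkm(reference)`; contigs with zero
#' reference RPKM get `NA` (undefined) and are excluded from downstream
#' summaries, unless `pseudocount` adds the same offset to both terms.
#' Each fold change is labelled with the strictest bias class it reaches:
#' `over50`/`under002` (beyond 50x), `over10`/`under01` (beyond 10x),
#' `neutral`, or `undefined`. Thresholds are strict inequalities.
#'
#' @param abundance `abundance_matrix` or rpkm matrix (contigs x samples).
#' @param reference_sample column name of the reference (e.g. unamplified)
#'   sample.
#' @param pseudocount optional value added to numerator and denominator;
#'   `NULL` keeps zero-reference contigs undefined.
#' @return data frame `contig_id`, `sample`, `fold_change`, `bias_class`.
#' @export
fold_changes <- function(abundance, reference_sample, pseudocount = NULL) {
  rpkm <- rpkm_of(abundance)
  if (!reference_sample %in% colnames(rpkm))
    stop(sprintf("reference sample %s not present", reference_sample))
  ref <- rpkm[, reference_sample]
  others <- setdiff(colnames(rpkm), reference_sample)
  out <- do.call(rbind, lapply(others, function(s) {
    x <- rpkm[, s]
    if (!is.null(pseudocount)) {
      fc <- (x + pseudocount) / (ref + pseudocount)
    } else {
      fc <- ifelse(ref == 0, NA_real_, x / ref)
    }
    data.frame(contig_id = rownames(rpkm), sample = s, fold_change = fc,
               bias_class = bias_class(fc), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

bias_class <- function(fc) {
  ifelse(is.na(fc), "undefined",
  ifelse(fc > 50, "over50",
  ifelse(fc < 0.02, "under002",
  ifelse(fc > 10, "over10",
  ifelse(fc < 0.1, "under01", "neutral")))))
}

#' Percentage of highly biased contigs
#'
#' Share of contigs with defined fold change lying strictly beyond the
#' symmetric threshold (`> threshold` or `< 1/threshold`), optionally over
#' a contig subset (e.g. excluding small circular contigs or extreme-GC
#' contigs when dissecting the sources of bias).
#'
#' @param fc_table output of [fold_changes()] (optionally pre-filtered to
#'   one sample), or a numeric vector of fold changes.
#' @param threshold fold-change threshold (e.g. 10 or 50).
#' @param subset optional logical vector or contig-id character vector
#'   selecting the contigs to consider.
#' @return percentage in `[0, 100]`.
#' @export
classify_biased_fraction <- function(fc_table, threshold = 10, subset = NULL) {
  fc <- if (is.data.frame(fc_table)) fc_table$fold_change else fc_table
  if (!is.null(subset)) {
    keep <- if (is.character(subset)) fc_table$contig_id %in% subset else subset
    fc <- fc[keep]
  }
  fc <- fc[!is.na(fc)]
  if (length(fc) == 0L) stop("no contigs with defined fold change after filtering")
  100 * sum(fc > threshold | fc < 1 / threshold) / length(fc)
}

#' Read GC-content histogram
#'
#' Relative abundance of reads as a function of their average GC content,
#' in right-open bins on `[0, 100]` (the last bin is closed).
#'
#' @param reads read table.
#' @param bin_width_pct bin width in %GC.
#' @return data frame `bin_lo`, `bin_hi`, `relative_abundance` (sums to 1).
#' @export
read_gc_histogram <- function(reads, bin_width_pct = 2) {
  if (nrow(reads) == 0L) stop("reads must be nonempty")
  gc <- gc_content(reads$seq, as_pct = TRUE)
  gc <- gc[!is.na(gc)]
  edges <- seq(0, 100, by = bin_width_pct)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  bin <- findInterval(gc, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             relative_abundance = counts / sum(counts))
}

#' Linear regression of log10 fold change on contig GC content
#'
#' Fits `log10(fold_change) ~ %GC` over contigs whose GC lies in
#' `gc_range`, optionally excluding circular contigs (whose fold changes
#' are dominated by rolling-circle over-amplification rather than the GC
#' response).
#'
#' @param fc_table [fold_changes()] rows for a single sample.
#' @param contigs contig table (supplies sequence GC and topology).
#' @param gc_range numeric `(lo, hi)` in %GC.
#' @param exclude_circular drop circular contigs before fitting.
#' @return list: `slope`, `intercept`, `n_contigs`, `gc_range`.
#' @export
gc_fold_regression <- function(fc_table, contigs, gc_range = c(30, 55),
                               exclude_circular = TRUE) {
  gc <- setNames(gc_content(contigs$seq, as_pct = TRUE), contigs$id)
  topo <- setNames(contigs$topology, contigs$id)
  d <- fc_table[!is.na(fc_table$fold_change) & fc_table$fold_change > 0, ]
  d$gc <- gc[d$contig_id]
  d <- d[d$gc >= gc_range[1] & d$gc <= gc_range[2], ]
  if (exclude_circular) d <- d[topo[d$contig_id] != "circular", ]
  if (nrow(d) < 3) stop("fewer than 3 contigs with defined fold change in range")
  fit <- lm(log10(fold_change) ~ gc, data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_contigs = nrow(d), gc_range = gc_range)
}

#' Read/write an RPKM table as TSV
#'
#' Layout: first column `contig_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return [read_rpkm_table()]: rpkm matrix (contigs x samples).
#' @export
read_rpkm_table <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_rpkm_table
#' @param rpkm rpkm matrix or `abundance_matrix`.
#' @export
write_rpkm_table <- function(rpkm, path) {
  m <- rpkm_of(rpkm)
  d <- data.frame(contig_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
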