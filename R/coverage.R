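#' Per-base coverage profile of a contig
#'
#' Depth at position `i` (0-based) is the number of retained alignments
#' whose half-open interval contains `i`; interval arithmetic is delegated
#' to IRanges coverage.
#'
#' @param alignments alignment data frame (rows for other contigs are
#'   ignored).
#' @param contig single-row contig table.
#' @return integer vector of length `contig$length_nt`.
#' @export
build_coverage <- function(alignments, contig) {
  stopifnot(nrow(contig) == 1L)
  a <- alignments[alignments$contig_id == contig$id, , drop = FALSE]
  L <- contig$length_nt
  if (nrow(a) == 0L) return(integer(L))
  if (any(a$start < 0) || any(a$end > L) || any(a$start >= a$end))
    stop("alignment interval out of contig bounds")
  ir <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  as.integer(IRanges::coverage(ir, width = L))
}

#' Trimmed coefficient of coverage variation
#'
#' Sample standard deviation over mean of per-base depth after discarding
#' `floor(trim_fraction * L)` positions from each contig end, so terminal
#' coverage ramps do not dominate the statistic.
#'
#' @param depth integer/numeric coverage vector.
#' @param trim_fraction fraction of positions removed from each end.
#' @return CV (>= 0), or `NA` when the trimmed interior has zero mean.
#' @export
coverage_cv <- function(depth, trim_fraction = 0.05) {
  L <- length(depth)
  k <- floor(trim_fraction * L)
  interior <- depth[seq.int(k + 1L, L - k)]
  if (length(interior) < 2L) stop("trimmed interior too short")
  m <- mean(interior)
  if (m == 0) return(NA_real_)
  sd(interior) / m
}

#' Lorenz curve and Gini coefficient of coverage
#'
#' Positions are sorted by increasing depth; the curve plots the cumulative
#' fraction of positions against the cumulative fraction of total coverage.
#' Perfectly even coverage traces the diagonal (Gini 0); concentration of
#' coverage into few positions bends the curve away (Gini -> 1). The Gini
#' is twice the trapezoidal area between the diagonal and the curve.
#'
#' @param depth coverage vector with positive total.
#' @return list: `lorenz` (data frame `pos_frac`, `cov_frac`, starting at
#'   (0,0) and ending at (1,1)) and `gini`.
#' @export
lorenz_curve <- function(depth) {
  tot <- sum(depth)
  if (tot <= 0) stop("total depth must be positive")
  d <- sort(as.numeric(depth))
  x <- c(0, seq_along(d) / length(d))
  y <- c(0, cumsum(d) / tot)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  list(lorenz = data.frame(pos_frac = x, cov_frac = y), gini = 1 - 2 * auc)
}

#' Pearson correlation between coverage profiles of the same contig
#'
#' @param a,b coverage vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA` if either profile is constant.
#' @export
profile_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Detect high-coverage peaks
#'
#' Sliding windows whose mean depth exceeds `fold_over_median` times the
#' contig-wide median depth are merged (maximal runs of step-adjacent
#' flagged windows) into peak intervals. The window/step/threshold
#' parametrisation is configurable since "a peak" has no universal
#' definition; the defaults suit the abrupt localized pile-ups produced by
#' primer-anchored amplification.
#'
#' @param depth coverage vector.
#' @param window_nt window width.
#' @param step_nt step between window starts.
#' @param fold_over_median flag windows above this multiple of the median.
#' @return data frame `start` (0-based), `end` (exclusive), `peak_mean`,
#'   `fold`; zero rows when no peaks.
#' @export
detect_high_coverage_peaks <- function(depth, window_nt = 50, step_nt = 20,
                                       fold_over_median = 5) {
  L <- length(depth)
  med <- median(depth)
  if (med <= 0) return(NA)
  starts <- seq.int(1L, L - window_nt + 1L, by = step_nt)
  cs <- c(0, cumsum(as.numeric(depth)))
  wmean <- (cs[starts + window_nt] - cs[starts]) / window_nt
  flagged <- wmean > fold_over_median * med
  if (!any(flagged))
    return(data.frame(start = integer(), end = integer(),
                      peak_mean = numeric(), fold = numeric()))
  runs <- rle(flagged)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  peaks <- which(runs$values)
  out <- lapply(peaks, function(p) {
    s <- starts[idx_start[p]] - 1L                     # 0-based
    e <- starts[idx_end[p]] + window_nt - 1L           # exclusive
    pm <- mean(depth[(s + 1L):e])
    data.frame(start = s, end = e, peak_mean = pm, fold = pm / med)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a coverage profile as mpileup-style TSV
#' @param depth coverage vector.
#' @param contig_id contig label.
#' @param path output path.
#' @export
write_coverage_tsv <- function(depth, contig_id, path) {
  write.table(data.frame(contig = contig_id, pos = seq_along(depth),
                         depth = as.integer(depth)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
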