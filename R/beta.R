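#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical profiles, 1 for disjoint
#' supports. `NA` when both vectors are all-zero.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]` or `NA`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  tot <- sum(x + y)
  if (tot == 0) return(NA_real_)
  sum(abs(x - y)) / tot
}

#' Sorensen (presence/absence) dissimilarity
#'
#' `1 - 2|A & B| / (|A| + |B|)` over the presence sets
#' `A = {i: x_i > presence_threshold}` (likewise `B`). More sensitive than
#' Bray-Curtis to biases affecting the detection of rare members.
#'
#' @param x,y numeric vectors of equal length.
#' @param presence_threshold strict abundance threshold for presence.
#' @return dissimilarity in `[0, 1]`, `NA` when both presence sets are
#'   empty.
#' @export
sorensen <- function(x, y, presence_threshold = 0) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  a <- x > presence_threshold
  b <- y > presence_threshold
  if (!any(a) && !any(b)) return(NA_real_)
  1 - 2 * sum(a & b) / (sum(a) + sum(b))
}

#' Pairwise community dissimilarity matrix
#'
#' Bray-Curtis or Sorensen dissimilarities among samples of an RPKM
#' abundance matrix, via vegan.
#'
#' @param abundance `abundance_matrix` or rpkm matrix (contigs x samples).
#' @param metric `"bray_curtis"` or `"sorensen"`.
#' @param presence_threshold presence cut-off for Sorensen.
#' @return symmetric labelled matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(abundance,
                                 metric = c("bray_curtis", "sorensen"),
                                 presence_threshold = 0) {
  metric <- match.arg(metric)
  m <- t(rpkm_of(abundance))  # vegan wants samples as rows
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist((m > presence_threshold) * 1, method = "bray", binary = TRUE)
  }
  as.matrix(d)
}

#' Pearson correlations among sample contig profiles
#'
#' Pairwise Pearson correlation of per-contig RPKM vectors between samples.
#'
#' @param abundance `abundance_matrix` or rpkm matrix (contigs x samples).
#' @return sample x sample correlation matrix (`NA` for zero-variance
#'   samples).
#' @export
pearson_profile_matrix <- function(abundance) {
  m <- rpkm_of(abundance)
  v <- apply(m, 2, var)
  out <- suppressWarnings(cor(m))
  out[v == 0, ] <- NA_real_
  out[, v == 0] <- NA_real_
  diag(out)[v > 0] <- 1
  out
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via vegan's `metaMDS` (monotone regression with
#' multiple random restarts), deterministic for a fixed seed. The reported
#' configuration is the best over the restarts.
#'
#' @param dissim symmetric dissimilarity matrix (or `dist`).
#' @param dims embedding dimension.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return list of class `ordination_result`: `coordinates` (samples x
#'   dims), `stress` (stress-1 in `[0, 1]`), `seed`, `n_restarts`.
#' @export
nmds_ordination <- function(dissim, dims = 2, n_restarts = 20, seed = 1) {
  d <- stats::as.dist(dissim)
  if (attr(d, "Size") < 3) stop("at least 3 samples are required")
  fit <- with_seed(seed, vegan::metaMDS(d, k = dims, try = n_restarts,
                                        trymax = max(n_restarts, 20),
                                        trace = 0, autotransform = FALSE,
                                        wascores = FALSE))
  structure(list(coordinates = vegan::scores(fit, display = "sites"),
                 stress = fit$stress, seed = seed, n_restarts = n_restarts),
            class = "ordination_result")
}

#' Resampled homologous-read sharing between two viromes
#'
#' Per iteration, one subsample is drawn from each virome and the number of
#' queries from the first subsample with at least one hit in the second is
#' counted (one-direction comparison). When both inputs are the same
#' virome, a read's hit to itself (same read id) is excluded, so the
#' statistic measures genuine sequence sharing. The default hit rule is an
#' ungapped local-homology surrogate for a stringent nucleotide BLAST
#' (alignment of at least `min_len` bases at `min_ident` identity, either
#' orientation); `rule = "exact"` requires an identical sequence.
#'
#' @param virome_a,virome_b read tables.
#' @param subsample_size reads drawn from each virome per iteration.
#' @param n_iterations number of resampling iterations.
#' @param rule `"local"` or `"exact"`.
#' @param min_len,min_ident local-rule thresholds.
#' @param seed integer seed.
#' @return list of class `sharing_distribution`: `counts` (one per
#'   iteration), `mean`, `sd`, `subsample_size`, `n_iterations`.
#' @export
homologous_read_sharing <- function(virome_a, virome_b, subsample_size = 10000,
                                    n_iterations = 10000,
                                    rule = c("local", "exact"),
                                    min_len = 100, min_ident = 0.9, seed = 1) {
  rule <- match.arg(rule)
  if (nrow(virome_a) < subsample_size || nrow(virome_b) < subsample_size)
    stop("collections must contain at least subsample_size reads")
  counts <- with_seed(seed, vapply(seq_len(n_iterations), function(i) {
    ia <- sample.int(nrow(virome_a), subsample_size)
    ib <- sample.int(nrow(virome_b), subsample_size)
    qa <- virome_a[ia, ]
    tb <- virome_b[ib, ]
    if (rule == "exact") {
      tseq <- c(tb$seq, revcomp(tb$seq))
      tid <- c(tb$id, tb$id)
      hit <- vapply(seq_len(nrow(qa)), function(j) {
        m <- tseq == qa$seq[j]
        any(m & tid != qa$id[j])
      }, TRUE)
      sum(hit)
    } else {
      sum(share_hits_cpp(qa$id, qa$seq, tb$id, tb$seq,
                         min_len = min_len, min_ident = min_ident))
    }
  }, 0L))
  structure(list(counts = counts, mean = mean(counts), sd = sd(counts),
                 subsample_size = subsample_size,
                 n_iterations = n_iterations),
            class = "sharing_distribution")
}

#' Compare two sharing distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with tie correction: exact enumeration
#' when both samples have at most 8 untied observations, normal
#' approximation otherwise.
#'
#' @param inter,intra numeric vectors (e.g. `counts` of two
#'   `sharing_distribution`s).
#' @return list: `U`, `p_value`.
#' @export
compare_sharing <- function(inter, intra) {
  if (length(inter) == 0 || length(intra) == 0) stop("empty input")
  ties <- anyDuplicated(c(inter, intra)) > 0
  exact <- length(inter) <= 8 && length(intra) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(inter, intra, exact = exact,
                                     correct = !exact))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}
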