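#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a serial dilution of
#' standards with known copy number. Amplification efficiency follows the
#' standard qPCR convention `(10^(-1/slope) - 1) * 100`, so a slope of
#' -3.3219 (perfect per-cycle doubling) gives 100%.
#'
#' @param standards data frame with columns `copies` (> 0) and `cq`;
#'   replicates may appear as repeated rows.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct`, `dynamic_range_logs`, `cq_range`.
#' @export
fit_standard_curve <- function(standards) {
  if (any(standards$copies <= 0)) stop("standard copies must be > 0")
  lg <- log10(standards$copies)
  if (length(unique(lg)) < 3)
    stop("at least 3 distinct dilution levels are required")
  fit <- lm(cq ~ lg, data = data.frame(cq = standards$cq, lg = lg))
  slope <- unname(coef(fit)[2])
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency_pct = (10^(-1 / slope) - 1) * 100,
    dynamic_range_logs = diff(range(lg)),
    cq_range = range(standards$cq)), class = "standard_curve")
}

#' Absolute quantification by interpolation on a standard curve
#'
#' Technical replicates are aggregated as the mean Cq *before* conversion,
#' then `copies = 10^((mean_cq - intercept) / slope)`. A measurement whose
#' mean Cq falls outside the calibrated Cq range is still converted but
#' flagged as an extrapolation.
#'
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param cq_replicates numeric vector of replicate Cq values; `NA` entries
#'   (no amplification) are dropped, and an all-`NA` input is treated as
#'   undetermined: zero copies with `censored = TRUE`.
#' @return list: `copies`, `mean_cq`, `extrapolated`, `censored`.
#' @export
quantify_absolute <- function(curve, cq_replicates) {
  if (length(cq_replicates) == 0) stop("cq_replicates must be nonempty")
  cq <- cq_replicates[!is.na(cq_replicates)]
  if (length(cq) == 0)
    return(list(copies = 0, mean_cq = NA_real_, extrapolated = FALSE,
                censored = TRUE))
  mean_cq <- mean(cq)
  list(copies = 10^((mean_cq - curve$intercept) / curve$slope),
       mean_cq = mean_cq,
       extrapolated = mean_cq < curve$cq_range[1] || mean_cq > curve$cq_range[2],
       censored = FALSE)
}

#' Quantify a Cq table of samples against per-virus standard curves
#'
#' @param standards data frame `virus`, `copies`, `cq` (replicate rows).
#' @param samples data frame `virus`, `sample`, `cq` (replicate rows).
#' @return data frame `virus`, `sample`, `mean_cq`, `copies`,
#'   `extrapolated`, `censored`: one row per (virus, sample).
#' @export
quantify_samples <- function(standards, samples) {
  curves <- lapply(split(standards, standards$virus), fit_standard_curve)
  grp <- split(samples, list(samples$virus, samples$sample), drop = TRUE)
  out <- lapply(grp, function(g) {
    q <- quantify_absolute(curves[[g$virus[1]]], g$cq)
    data.frame(virus = g$virus[1], sample = g$sample[1], mean_cq = q$mean_cq,
               copies = q$copies, extrapolated = q$extrapolated,
               censored = q$censored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$virus), ]
}

#' Community composition from absolute genome counts
#'
#' @param measurements data frame with columns `virus`, `sample`, `copies`.
#' @return data frame `virus`, `sample`, `copies`,
#'   `relative_proportion_pct`; proportions sum to 100 within each sample.
#' @export
community_composition <- function(measurements) {
  grp <- split(measurements, measurements$sample)
  out <- lapply(grp, function(g) {
    tot <- sum(g$copies)
    if (tot <= 0) stop(sprintf("sample %s has zero total copies", g$sample[1]))
    g$relative_proportion_pct <- 100 * g$copies / tot
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("virus", "sample", "copies", "relative_proportion_pct")]
}

#' Per-virus fold changes between two composition tables
#'
#' Fold change of either the total genome amount (`copies`) or the relative
#' proportion, after/before. A zero "before" value yields `NA` (undefined);
#' a zero "after" over a positive "before" yields 0.
#'
#' @param before,after composition tables ([community_composition()]) for a
#'   single sample each, covering the same virus set.
#' @param mode `"total_amount"` or `"relative_proportion"`.
#' @return data frame `virus`, `before`, `after`, `fold_change`.
#' @export
treatment_fold_changes <- function(before, after,
                                   mode = c("total_amount",
                                            "relative_proportion")) {
  mode <- match.arg(mode)
  if (!setequal(before$virus, after$virus))
    stop("before and after tables must cover the same virus set")
  col <- if (mode == "total_amount") "copies" else "relative_proportion_pct"
  b <- setNames(before[[col]], before$virus)
  a <- setNames(after[[col]], after$virus)[names(b)]
  fc <- ifelse(b == 0, NA_real_, a / b)
  data.frame(virus = names(b), before = unname(b), after = unname(a),
             fold_change = unname(fc), stringsAsFactors = FALSE)
}
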