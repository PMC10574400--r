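#' Construct a time-course count object
#'
#' @param counts gene x sample matrix of non-negative counts with row and
#'   column names.
#' @param samples data.frame with columns `sample_id`, `zt_hour`,
#'   `replicate`, one row per count column, in column order.
#' @return object of class `timecourse`.
#' @export
timecourse <- function(counts, samples) {
  counts <- as.matrix(counts)
  .check(!is.null(rownames(counts)) && !is.null(colnames(counts)),
         "counts must have gene rownames and sample colnames")
  .check(all(counts >= 0), "counts must be non-negative")
  .check(all(c("sample_id", "zt_hour") %in% names(samples)),
         "samples needs sample_id and zt_hour columns")
  .check(!anyDuplicated(samples$sample_id), "duplicate sample ids")
  .check(identical(colnames(counts), as.character(samples$sample_id)),
         "count columns must match samples$sample_id in order")
  .check(!anyNA(samples$zt_hour), "every sample needs a ZT hour")
  structure(list(counts = counts, samples = samples), class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("timecourse: %d genes x %d samples, ZT %g..%g\n",
              nrow(x$counts), ncol(x$counts),
              min(x$samples$zt_hour), max(x$samples$zt_hour)))
  invisible(x)
}

#' Filter genes with sufficiently large counts
#'
#' Keeps genes whose CPM exceeds the CPM equivalent of `min_count` at the
#' median library size in at least `ceiling(min_samples_frac * n_samples)`
#' samples, and whose total count exceeds `min_total`. This mirrors the
#' contract of the usual expressed-gene filter for count matrices.
#'
#' @param tc a [timecourse()] object.
#' @param min_count minimum count at the median library size (default 10).
#' @param min_samples_frac fraction of samples that must pass; default
#'   `1 / n_timepoints` (one replicate group's worth).
#' @param min_total floor on the total count across samples (default 15).
#' @return character vector of kept gene ids, input order preserved; a
#'   warning (not an error) and an empty vector if nothing survives.
#' @export
filter_expressed <- function(tc, min_count = 10, min_samples_frac = NULL,
                             min_total = 15) {
  .check(inherits(tc, "timecourse"), "tc must be a timecourse")
  .check(min_count >= 0, "min_count must be >= 0")
  if (is.null(min_samples_frac)) {
    min_samples_frac <- 1 / length(unique(tc$samples$zt_hour))
  }
  lib <- colSums(tc$counts)
  cpm_cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- t(t(tc$counts) / lib) * 1e6
  k <- ceiling(min_samples_frac * ncol(tc$counts))
  keep <- rowSums(cpm >= cpm_cutoff) >= k & rowSums(tc$counts) > min_total
  if (!any(keep)) warning("no genes pass the expression filter")
  rownames(tc$counts)[keep]
}

#' Trimmed-mean-of-log-ratios library scaling factors
#'
#' For each sample, log2 ratios of relative abundance against a reference
#' sample are computed over genes expressed in both; ratios in the upper and
#' lower `trim_logratio` tails, and genes in the upper and lower `trim_abs`
#' tails of average absolute intensity, are trimmed; the factor is 2 to the
#' mean of the surviving log ratios. Factors are rescaled so their geometric
#' mean is 1. A sample with zero total count is an error naming the sample.
#'
#' @param tc a [timecourse()] object.
#' @param trim_logratio fraction trimmed from each tail of the log-ratios
#'   (default 0.3).
#' @param trim_abs fraction trimmed from each tail of average intensity
#'   (default 0.05).
#' @param ref reference sample id; default is the sample whose upper
#'   quartile of CPM is closest to the across-sample mean upper quartile.
#' @return named numeric vector of per-sample scaling factors.
#' @export
scaling_factors <- function(tc, trim_logratio = 0.3, trim_abs = 0.05,
                            ref = NULL) {
  .check(inherits(tc, "timecourse"), "tc must be a timecourse")
  .check(ncol(tc$counts) >= 2, "need at least 2 samples")
  lib <- colSums(tc$counts)
  zero <- lib == 0
  .check(!any(zero), "sample(s) with zero total count: %s",
         paste(colnames(tc$counts)[zero], collapse = ", "))
  p <- t(t(tc$counts) / lib)  # relative abundance
  if (is.null(ref)) {
    uq <- apply(p, 2, stats::quantile, probs = 0.75)
    ref <- colnames(tc$counts)[which.min(abs(uq - mean(uq)))]
  }
  .check(ref %in% colnames(tc$counts), "unknown reference sample '%s'", ref)
  pr <- p[, ref]
  f <- vapply(colnames(tc$counts), function(s) {
    ps <- p[, s]
    ok <- ps > 0 & pr > 0
    if (sum(ok) < 1) return(1)
    M <- log2(ps[ok] / pr[ok])
    A <- 0.5 * log2(ps[ok] * pr[ok])
    keep <- M >= stats::quantile(M, trim_logratio) &
            M <= stats::quantile(M, 1 - trim_logratio) &
            A >= stats::quantile(A, trim_abs) &
            A <= stats::quantile(A, 1 - trim_abs)
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  f
}

#' log2 counts-per-million with effective library sizes
#'
#' `log2((count + prior_j) / (libsize_j * factor_j + 2 * prior_j) * 1e6)`
#' where `prior_j = prior_count * effective_libsize_j / 1e6`, i.e. the
#' pseudo-count is `prior_count` in CPM units. Consequences: rescaling all
#' counts by a common factor leaves the result exactly unchanged, and a
#' zero count maps to approximately `log2(prior_count)` in every sample.
#' Strictly increasing in each count.
#'
#' @param tc a [timecourse()] object.
#' @param factors per-sample scaling factors (default all 1).
#' @param prior_count pseudo-count (default 0.5).
#' @param keep optional gene ids to retain (e.g. from [filter_expressed()]).
#' @return object of class `normalized_matrix`: list with `log2cpm`
#'   (gene x sample), `weights` (NULL until [estimate_weights()]),
#'   `scaling_factors`, `kept_genes`, and `samples` (the sample sheet).
#' @export
log2_cpm <- function(tc, factors = NULL, prior_count = 0.5, keep = NULL) {
  .check(inherits(tc, "timecourse"), "tc must be a timecourse")
  if (is.null(factors)) factors <- rep(1, ncol(tc$counts))
  .check(all(factors > 0), "scaling factors must be positive")
  counts <- tc$counts
  if (!is.null(keep)) counts <- counts[keep, , drop = FALSE]
  eff <- colSums(tc$counts) * factors
  pr <- prior_count * eff / 1e6
  l2 <- log2(t((t(counts) + pr) / (eff + 2 * pr)) * 1e6)
  structure(list(log2cpm = l2, weights = NULL,
                 scaling_factors = stats::setNames(factors, colnames(counts)),
                 kept_genes = rownames(counts), samples = tc$samples),
            class = "normalized_matrix")
}

#' Estimate observation weights for the cosine fit
#'
#' Residuals are taken around per-timepoint means (replicates within a ZT
#' hour are the exchangeable unit in a time course). Modes:
#' \describe{
#'   \item{equal}{all weights exactly 1.}
#'   \item{mean_variance}{per gene, the inverse of the squared residual
#'     scale predicted from a lowess trend of sqrt residual sd versus
#'     average log2(CPM) (a precision-weight scheme in the voom spirit).}
#'   \item{per_sample_quality}{`mean_variance` weights multiplied by a
#'     per-sample factor inversely proportional to that sample's mean
#'     squared residual, normalized to mean 1.}
#'   \item{external}{weights supplied in `external` (matching dimensions).}
#' }
#' Weights are always strictly positive; values below 1e-6 are clipped with
#' a warning.
#'
#' @param norm a [log2_cpm()] object.
#' @param mode one of `"per_sample_quality"`, `"mean_variance"`, `"equal"`,
#'   `"external"`.
#' @param external gene x sample weight matrix for `mode = "external"`.
#' @param span lowess span for the mean-variance trend.
#' @return the `normalized_matrix` with its `weights` slot filled.
#' @export
estimate_weights <- function(norm,
                             mode = c("per_sample_quality", "mean_variance",
                                      "equal", "external"),
                             external = NULL, span = 0.5) {
  .check(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
  mode <- match.arg(mode)
  y <- norm$log2cpm
  if (mode == "equal") {
    norm$weights <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
    return(norm)
  }
  if (mode == "external") {
    .check(!is.null(external) && all(dim(external) == dim(y)),
           "external weights must match the matrix dimensions")
    w <- as.matrix(external)
  } else {
    grp <- factor(norm$samples$zt_hour)
    .check(nlevels(grp) < ncol(y), "need replicates within timepoints")
    G <- stats::model.matrix(~ 0 + grp)
    gm <- (y %*% G %*% diag(1 / colSums(G), nlevels(grp)))[, as.integer(grp)]
    resid <- y - gm
    df_res <- ncol(y) - nlevels(grp)
    sd_g <- sqrt(rowSums(resid^2) / df_res)
    mean_g <- rowMeans(y)
    lo <- stats::lowess(mean_g, sqrt(sd_g), f = span)
    pred <- stats::approx(lo$x, lo$y, xout = mean_g, rule = 2)$y
    pred <- pmax(pred, 0.05)  # sqrt-sd floor: variance floor 6.25e-6
    w_gene <- 1 / pred^4      # inverse predicted variance
    w <- matrix(w_gene, nrow(y), ncol(y), dimnames = dimnames(y))
    if (mode == "per_sample_quality") {
      msr <- colMeans(resid^2)
      fac <- 1 / pmax(msr, 1e-12)
      fac <- fac / mean(fac)
      w <- sweep(w, 2, fac, "*")
    }
    w <- w / mean(w)  # overall scale is arbitrary in WLS; contract: mean 1
  }
  if (any(w < 1e-6)) {
    warning("non-positive/tiny weights clipped to 1e-6")
    w[w < 1e-6] <- 1e-6
  }
  norm$weights <- w
  norm
}

#' Sample-sample Pearson correlation on log2(CPM)
#'
#' Checks reproducibility of the time course: replicate samples and samples
#' 24 h apart should correlate more highly than samples 12 h apart
#' (antiphase for a ~24 h oscillation). Zero-variance samples yield NA for
#' their pairs.
#'
#' @param norm a [log2_cpm()] object.
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(norm) {
  .check(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
  .check(ncol(norm$log2cpm) >= 2, "need at least 2 samples")
  cc <- suppressWarnings(stats::cor(norm$log2cpm))
  diag(cc) <- 1
  cc
}

#' One-call preprocessing: filter, scale, log2(CPM), weights
#'
#' @param tc a [timecourse()] object.
#' @param min_count,min_samples_frac,min_total see [filter_expressed()].
#' @param trim_logratio,trim_abs see [scaling_factors()].
#' @param prior_count see [log2_cpm()].
#' @param weights_mode see [estimate_weights()].
#' @return a `normalized_matrix` with weights.
#' @export
preprocess <- function(tc, min_count = 10, min_samples_frac = NULL,
                       min_total = 15, trim_logratio = 0.3, trim_abs = 0.05,
                       prior_count = 0.5,
                       weights_mode = "per_sample_quality") {
  keep <- filter_expressed(tc, min_count, min_samples_frac, min_total)
  f <- scaling_factors(tc, trim_logratio, trim_abs)
  norm <- log2_cpm(tc, f, prior_count, keep = keep)
  estimate_weights(norm, mode = weights_mode)
}
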