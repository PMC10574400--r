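#' Classify rhythmic genes by oscillation-correlation cutoff
#'
#' A gene is rhythmic when its fit converged and its circadian oscillation
#' correlation is at least `cutoff` (the conventional robust threshold is
#' 0.7). Raising the cutoff never adds members.
#'
#' @param fits a fits table from [fit_all()].
#' @param cutoff correlation threshold in `[0, 1]`.
#' @param label source label (e.g. the species).
#' @return object of class `rhythmic_set`: list with `label`, `cutoff`,
#'   `members` (the rhythmic subset of the fits table) and `n_expressed`
#'   (size of the parent universe).
#' @export
classify_rhythmic <- function(fits, cutoff = 0.7, label = "setA") {
  .check(cutoff >= 0 && cutoff <= 1, "cutoff must be in [0, 1]")
  keep <- fits$converged & !is.na(fits$correlation) &
    fits$correlation >= cutoff
  structure(list(label = label, cutoff = cutoff,
                 members = fits[keep, , drop = FALSE],
                 n_expressed = nrow(fits)),
            class = "rhythmic_set")
}

#' @export
print.rhythmic_set <- function(x, ...) {
  cat(sprintf("rhythmic_set '%s': %d/%d genes at correlation >= %g\n",
              x$label, nrow(x$members), x$n_expressed, x$cutoff))
  invisible(x)
}

#' Rhythmic-gene counts and fractions across correlation cutoffs
#'
#' For each cutoff, the number of rhythmic genes and their fraction of the
#' expressed universe are computed for both fits tables; the two fraction
#' profiles are then compared with a two-sample Kolmogorov-Smirnov test
#' (the profiles are paired by cutoff, which the KS test ignores; this
#' matches the published analysis and is documented as such).
#'
#' @param fits_a,fits_b fits tables for the two sources.
#' @param cutoffs increasing vector of correlation cutoffs (>= 2 values).
#' @param labels length-2 source labels.
#' @return list with `table` (cutoff, label, n_rhythmic, fraction) and
#'   `test` (the `ks.test` result on the two fraction profiles).
#' @export
cutoff_sweep <- function(fits_a, fits_b, cutoffs = seq(0.5, 0.95, by = 0.05),
                         labels = c("A", "B")) {
  .check(length(cutoffs) >= 2, "need at least 2 cutoffs")
  .check(nrow(fits_a) > 0 && nrow(fits_b) > 0, "empty fits universe")
  one <- function(fits, lab) {
    n <- vapply(cutoffs, function(ct)
      nrow(classify_rhythmic(fits, ct, lab)$members), numeric(1))
    data.frame(cutoff = cutoffs, label = lab, n_rhythmic = n,
               fraction = n / nrow(fits), stringsAsFactors = FALSE)
  }
  tab <- rbind(one(fits_a, labels[1]), one(fits_b, labels[2]))
  fa <- tab$fraction[tab$label == labels[1]]
  fb <- tab$fraction[tab$label == labels[2]]
  test <- suppressWarnings(stats::ks.test(fa, fb))
  list(table = tab, test = test)
}

# internal: Kuiper two-sample test (circular-aware alternative to KS)
.kuiper_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  V <- max(Fx - Fy) + max(Fy - Fx)
  ne <- nx * ny / (nx + ny)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = V, p.value = max(min(p, 1), 0))
}

#' Compare a circadian parameter distribution between two rhythmic sets
#'
#' Two-sided Kolmogorov-Smirnov or Mann-Whitney (Wilcoxon rank-sum) test on
#' the two parameter vectors, with per-set medians and IQRs. Phase24 is a
#' circular quantity; by default it is treated linearly on `[0, 24)` (the
#' convention of the published comparison), with `circular = TRUE` running
#' a Kuiper-style test that is invariant to rotation of the phase origin.
#'
#' @param set_a,set_b `rhythmic_set` objects.
#' @param parameter one of `"phase24"`, `"period"`, `"amplitude"`,
#'   `"constant"`.
#' @param test `"ks"` or `"mann_whitney"`.
#' @param circular use the Kuiper variant (phase24 only).
#' @return data.frame of class `distribution_comparison` with parameter,
#'   test name, statistic, p-value and per-set summaries.
#' @export
compare_param <- function(set_a, set_b,
                          parameter = c("phase24", "period", "amplitude",
                                        "constant"),
                          test = c("ks", "mann_whitney"),
                          circular = FALSE) {
  parameter <- match.arg(parameter)
  test <- match.arg(test)
  xa <- set_a$members[[parameter]]
  xb <- set_b$members[[parameter]]
  .check(length(xa) >= 3 && length(xb) >= 3,
         "need at least 3 members per set")
  if (circular) {
    .check(parameter == "phase24", "circular test applies to phase24 only")
    ht <- .kuiper_test(xa, xb)
    stat <- ht$statistic; pval <- ht$p.value; tname <- "kuiper"
  } else if (test == "ks") {
    ht <- suppressWarnings(stats::ks.test(xa, xb))
    stat <- unname(ht$statistic); pval <- ht$p.value; tname <- "ks"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(xa, xb))
    stat <- unname(ht$statistic); pval <- ht$p.value; tname <- "mann_whitney"
  }
  structure(data.frame(parameter = parameter, test = tname,
                       statistic = stat, p_value = pval,
                       median_a = stats::median(xa),
                       iqr_a = stats::IQR(xa),
                       median_b = stats::median(xb),
                       iqr_b = stats::IQR(xb),
                       n_a = length(xa), n_b = length(xb),
                       stringsAsFactors = FALSE),
            class = c("distribution_comparison", "data.frame"))
}

#' Peaks of the circular phase24 density
#'
#' Kernel density of phase24 on the 24 h circle: phases are replicated at
#' -24 and +24 h before estimation so the estimate is edge-free, evaluated
#' on a 0.01 h grid over `[0, 24)` (rescaled to integrate to 1 on the
#' circle). Local maxima are returned sorted by height, so a phase
#' distribution with a major and minor peaks reports them in order.
#'
#' @param set a `rhythmic_set` (>= 50 members recommended for stability).
#' @param bandwidth kernel bandwidth in hours; default a Silverman-style
#'   rule clipped to `[0.5, 2]` h.
#' @return list with `peaks` (data.frame `phase`, `height`, sorted by
#'   descending height) and `density` (data.frame `phase`, `density` on the
#'   grid).
#' @export
phase_density_peaks <- function(set, bandwidth = NULL) {
  ph <- set$members$phase24
  .check(length(ph) >= 3, "need phases to estimate a density")
  if (is.null(bandwidth)) {
    bandwidth <- min(max(stats::bw.nrd0(ph), 0.5), 2)
  }
  .check(bandwidth > 0, "bandwidth must be positive")
  rep3 <- c(ph - 24, ph, ph + 24)
  grid_n <- 2400
  d <- stats::density(rep3, bw = bandwidth, from = 0, to = 24 - 24 / grid_n,
                      n = grid_n)
  dens <- d$y * 3  # a third of the replicated mass lies in [0, 24)
  nx <- length(dens)
  left <- dens[c(nx, seq_len(nx - 1))]   # circular neighbours
  right <- dens[c(seq_len(nx - 1) + 1, 1)]
  is_peak <- dens > left & dens >= right
  peaks <- data.frame(phase = d$x[is_peak], height = dens[is_peak])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, density = data.frame(phase = d$x, density = dens))
}
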