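#' Holm-Sidak step-down adjustment of a family of p-values
#'
#' Sorted raw p-values receive `adj_i = 1 - (1 - p_(i))^(m - i + 1)`,
#' enforced monotone non-decreasing, capped at 1. With m = 1 the adjusted
#' p equals the raw p.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
adjust_holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# internal: significance stars at 0.05 / 0.01 / 0.001
.stars <- function(p) {
  as.character(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")))
}

#' Contrast a fitted parameter between a reference gene and its homologs
#'
#' Each homolog is compared against the reference with a Welch-style
#' statistic on the fitted estimates: `t = diff / sqrt(se_h^2 + se_r^2)`
#' with Satterthwaite degrees of freedom from the two fits' residual df,
#' two-sided p. Phase24 differences are computed on the circle (wrapped to
#' `(-12, 12]`). The family of comparisons for one reference gene is
#' adjusted by Holm-Sidak, with significance stars at 0.05/0.01/0.001.
#' Homologs with missing standard errors are skipped with a warning.
#'
#' @param ref_fit one-row fits table for the reference gene.
#' @param homolog_fits fits table for its homologs (one row each).
#' @param parameter one of `"period"`, `"amplitude"`, `"phase24"`,
#'   `"constant"`.
#' @return data.frame with one row per homolog: reference and homolog gene,
#'   estimates, `difference`, `statistic`, `df`, `p_raw`, `p_adj`, `stars`.
#' @export
contrast_parameters <- function(ref_fit, homolog_fits,
                                parameter = c("period", "amplitude",
                                              "phase24", "constant")) {
  parameter <- match.arg(parameter)
  se_col <- c(period = "period_se", amplitude = "amp_se",
              phase24 = "phase24_se", constant = "const_se")[parameter]
  .check(nrow(ref_fit) == 1, "ref_fit must be a single fit row")
  .check(isTRUE(ref_fit$converged), "reference fit did not converge")
  ok <- homolog_fits$converged & is.finite(homolog_fits[[se_col]])
  if (!all(ok)) {
    warning(sprintf("%d homolog(s) skipped (non-converged or missing SE)",
                    sum(!ok)))
    homolog_fits <- homolog_fits[ok, , drop = FALSE]
  }
  m <- nrow(homolog_fits)
  if (m == 0) return(NULL)
  e_r <- ref_fit[[parameter]]; se_r <- ref_fit[[se_col]]; df_r <- ref_fit$df
  e_h <- homolog_fits[[parameter]]; se_h <- homolog_fits[[se_col]]
  df_h <- homolog_fits$df
  d <- e_h - e_r
  if (parameter == "phase24") d <- wrap_phase_diff(d)
  v <- se_h^2 + se_r^2
  tstat <- ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, Inf))
  dfw <- ifelse(v > 0, v^2 / (se_h^4 / df_h + se_r^4 / df_r), df_r)
  p_raw <- ifelse(is.finite(tstat),
                  2 * stats::pt(-abs(tstat), dfw),
                  0)
  p_raw[v == 0 & d == 0] <- 1
  p_adj <- adjust_holm_sidak(p_raw)
  data.frame(ref_gene = ref_fit$gene, homolog = homolog_fits$gene,
             parameter = parameter, estimate_ref = e_r, estimate_hom = e_h,
             difference = d, statistic = tstat, df = dfw, p_raw = p_raw,
             p_adj = p_adj, stars = .stars(p_adj),
             stringsAsFactors = FALSE)
}

#' Replicate-level one-way ANOVA route for homolog contrasts
#'
#' When per-replicate parameter values are available (one value per
#' biological replicate per gene), this runs a one-way ANOVA across all
#' groups followed by per-homolog-vs-reference comparisons using the pooled
#' residual mean square, adjusted by Holm-Sidak.
#'
#' @param ref_values numeric vector of replicate-level values for the
#'   reference gene.
#' @param homolog_values named list of numeric vectors, one per homolog.
#' @return data.frame with per-homolog `difference`, `statistic`, `df`,
#'   `p_raw`, `p_adj`, `stars`; the overall ANOVA p-value is attached as
#'   attribute `anova_p`.
#' @export
contrast_parameters_anova <- function(ref_values, homolog_values) {
  .check(length(homolog_values) >= 1 && !is.null(names(homolog_values)),
         "homolog_values must be a named list")
  groups <- c(list(.ref = ref_values), homolog_values)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  mr <- mean(ref_values); nr <- length(ref_values)
  rows <- lapply(names(homolog_values), function(g) {
    x <- homolog_values[[g]]
    d <- mean(x) - mr
    se <- sqrt(mse * (1 / length(x) + 1 / nr))
    tstat <- d / se
    data.frame(homolog = g, difference = d, statistic = tstat, df = dfe,
               p_raw = 2 * stats::pt(-abs(tstat), dfe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_holm_sidak(out$p_raw)
  out$stars <- .stars(out$p_adj)
  attr(out, "anova_p") <- an["group", "Pr(>F)"]
  out
}

#' Radial-plot coordinates for fitted genes
#'
#' Phase24 maps to the angular coordinate (`2*pi*phase24/24`), oscillation
#' robustness to the radius (`-log10(p_rhythm)`, capped at 300 so perfect
#' fits stay plottable), and the phase24 standard error to the symbol size.
#' Genes with missing p-values are omitted with a warning.
#'
#' @param fits fits table (converged rows are used).
#' @return data.frame with `gene`, `angle` (radians in `[0, 2*pi)`),
#'   `radius`, `size`.
#' @export
radial_coordinates <- function(fits) {
  keep <- fits$converged & !is.na(fits$p_rhythm)
  if (any(fits$converged & is.na(fits$p_rhythm))) {
    warning("points with missing p omitted")
  }
  f <- fits[keep, , drop = FALSE]
  data.frame(gene = f$gene,
             angle = 2 * pi * f$phase24 / 24,
             radius = pmin(-log10(pmax(f$p_rhythm, 1e-300)), 300),
             size = f$phase24_se,
             stringsAsFactors = FALSE)
}

#' Long-format expression-profile table for a set of genes
#'
#' For expression-profile plots of a clock gene and its homologs: one row
#' per observation (gene, ZT hour, replicate, log2(CPM)) plus the
#' model-predicted value at that time from the gene's fit.
#'
#' @param fits fits table containing the genes.
#' @param norm the `normalized_matrix` the fits were computed from.
#' @param genes gene ids to include (default: all genes in `fits`).
#' @return data.frame with `gene`, `zt_hour`, `replicate`, `log2cpm`,
#'   `predicted`.
#' @export
profile_table <- function(fits, norm, genes = fits$gene) {
  missing <- setdiff(genes, rownames(norm$log2cpm))
  .check(length(missing) == 0, "gene(s) not in matrix: %s",
         paste(missing, collapse = ", "))
  missing_fit <- setdiff(genes, fits$gene)
  .check(length(missing_fit) == 0, "gene(s) not in fits: %s",
         paste(missing_fit, collapse = ", "))
  t <- norm$samples$zt_hour
  rows <- lapply(genes, function(g) {
    fit <- fits[fits$gene == g, , drop = FALSE]
    data.frame(gene = g, zt_hour = t, replicate = norm$samples$replicate,
               log2cpm = norm$log2cpm[g, ],
               predicted = predict_cos(fit, t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
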