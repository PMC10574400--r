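# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive re-derivations (explicit loops, closed
# forms) kept independent of the package implementation paths they check.

# default free-running design times: 12 timepoints, 4 h apart, from ZT24
tt_default <- function(reps = 2) rep(seq(24, 68, by = 4), each = reps)

# exact cosine curve in the model's parameterization
make_cos <- function(t, A, P, ph, C = 0) {
  A * cos(2 * pi * t / P - 2 * pi * ph / 24) + C
}

# Grid-search oracle for the weighted cosine fit: amplitude/constant by
# closed-form weighted linear solve at every (period, phase) node. The
# per-period sums are expanded with the angle-addition identity so the
# phase grid is vectorized.
oracle_grid_sse <- function(t, y, w, period_step = 0.01, phase_step = 0.05,
                            period_bounds = c(12, 36)) {
  phases <- seq(0, 24 - phase_step, by = phase_step)
  cph <- cos(2 * pi * phases / 24)
  sph <- sin(2 * pi * phases / 24)
  Sw <- sum(w); Sy <- sum(w * y); Syy <- sum(w * y^2)
  best <- Inf
  for (P in seq(period_bounds[1] + period_step,
                period_bounds[2] - period_step, by = period_step)) {
    wt <- 2 * pi * t / P
    cc <- cos(wt); ss <- sin(wt)
    # c = cos(wt - phr) = cc*cph + ss*sph for each phase
    Sc  <- cph * sum(w * cc) + sph * sum(w * ss)
    Scc <- cph^2 * sum(w * cc^2) + 2 * cph * sph * sum(w * cc * ss) +
           sph^2 * sum(w * ss^2)
    Scy <- cph * sum(w * cc * y) + sph * sum(w * ss * y)
    den <- Sw * Scc - Sc^2
    A <- (Sw * Scy - Sc * Sy) / den
    C <- (Sy - A * Sc) / Sw
    sse <- Syy - 2 * A * Scy - 2 * C * Sy + A^2 * Scc + 2 * A * C * Sc +
      C^2 * Sw
    m <- min(sse[is.finite(sse)])
    if (m < best) best <- m
  }
  best
}

# brute-force enrichment running sum, literal step-by-step walk
oracle_es <- function(genes_ranked, scores, gene_set, p = 1) {
  N <- length(genes_ranked)
  hit <- genes_ranked %in% gene_set
  n <- sum(hit)
  NR <- sum(abs(scores[hit])^p)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      acc <- acc + (if (NR > 0) abs(scores[i])^p / NR else 1 / n)
    } else {
      acc <- acc - 1 / (N - n)
    }
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# step-by-step trimmed-mean scaling factor for one sample against a
# reference, following the stated definition literally
oracle_tmm_factor <- function(x, r, trim_logratio = 0.3, trim_abs = 0.05) {
  px <- x / sum(x); pr <- r / sum(r)
  ok <- px > 0 & pr > 0
  M <- log2(px[ok] / pr[ok])
  A <- 0.5 * log2(px[ok] * pr[ok])
  qM <- quantile(M, c(trim_logratio, 1 - trim_logratio))
  qA <- quantile(A, c(trim_abs, 1 - trim_abs))
  keep <- M >= qM[1] & M <= qM[2] & A >= qA[1] & A <= qA[2]
  2^mean(M[keep])
}

# closed-form weighted simple regression via normal equations
oracle_wls_line <- function(t, y, w) {
  Sw <- sum(w); St <- sum(w * t); Stt <- sum(w * t^2)
  Sy <- sum(w * y); Sty <- sum(w * t * y)
  slope <- (Sw * Sty - St * Sy) / (Sw * Stt - St^2)
  intercept <- (Sy - slope * St) / Sw
  c(intercept = intercept, slope = slope)
}

# build a minimal normalized_matrix around a bare expression matrix
as_norm <- function(mat, design, weights = NULL) {
  structure(list(log2cpm = mat, weights = weights,
                 scaling_factors = rep(1, ncol(mat)),
                 kept_genes = rownames(mat), samples = design$samples),
            class = "normalized_matrix")
}

# fits-table stub with the columns classify/compare/contrast consume
fits_stub <- function(gene, correlation, period = 24, amplitude = 1,
                      phase24 = 6, constant = 5, p_rhythm = 0.01,
                      se = 0.1, df = 20) {
  data.frame(gene = gene, amplitude = amplitude, amp_se = se,
             period = period, period_se = se, phase24 = phase24,
             phase24_se = se, constant = constant, const_se = se,
             trend_slope = 0, df = df, correlation = correlation,
             p_rhythm = p_rhythm, sse = 1, sse0 = 2, converged = TRUE,
             at_bound = FALSE, stringsAsFactors = FALSE)
}
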