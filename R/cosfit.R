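#' Fit settings for the cosine oscillation model
#'
#' @param period_min,period_max hard period bounds in hours; the free-running
#'   period is constrained to be greater than 12 h and less than 36 h.
#' @param grid_step spacing (h) of the coarse period grid scanned before
#'   local refinement.
#' @param tol absolute tolerance (h) of the golden-section period
#'   refinement.
#' @param use_weights if FALSE, weights are ignored (set to 1).
#' @return list of class `fit_settings`.
#' @export
fit_settings <- function(period_min = 12, period_max = 36, grid_step = 0.5,
                         tol = 1e-9, use_weights = TRUE) {
  .check(period_min < period_max, "period bounds must be ordered")
  .check(grid_step > 0 && tol > 0, "grid_step and tol must be positive")
  structure(list(period_min = period_min, period_max = period_max,
                 grid_step = grid_step, tol = tol,
                 use_weights = use_weights),
            class = "fit_settings")
}

#' Remove a linear trend by weighted least squares
#'
#' Fits `value ~ time` with weights and returns the residuals together with
#' the removed slope and intercept. Residuals have weighted mean zero and
#' zero weighted covariance with time.
#'
#' @param times hours.
#' @param values expression values (log2 scale).
#' @param weights positive weights (default all 1).
#' @return list with `residuals`, `slope`, `intercept`.
#' @export
#' @examples
#' d <- detrend(0:10, 2 * (0:10) + 5)
#' d$slope             # 2
#' max(abs(d$residuals))
detrend <- function(times, values, weights = NULL) {
  n <- length(times)
  .check(n >= 3, "need at least 3 points")
  .check(length(values) == n, "times and values differ in length")
  if (is.null(weights)) weights <- rep(1, n)
  .check(all(weights > 0), "weights must be positive")
  .check(stats::sd(times) > 0, "constant time vector")
  tb <- .wmean(times, weights)
  yb <- .wmean(values, weights)
  slope <- sum(weights * (times - tb) * (values - yb)) /
    sum(weights * (times - tb)^2)
  intercept <- yb - slope * tb
  list(residuals = values - intercept - slope * times,
       slope = slope, intercept = intercept)
}

#' FFT-based initial period and phase estimate
#'
#' Operates on the per-timepoint mean series of detrended residuals
#' (replicates averaged so the series is uniformly spaced). The dominant
#' in-bounds spectral peak is kept as the "main signal": the maximal-power
#' frequency bin whose period lies strictly inside `period_bounds`, refined
#' by quadratic interpolation of log power across the peak bin and its
#' neighbours. If no in-bounds bin exists (or the series is flat), a 24 h
#' fallback is returned with `in_bounds = FALSE`.
#'
#' @param series per-timepoint mean residuals, uniformly spaced.
#' @param interval_h hours between consecutive points.
#' @param period_bounds open period interval, default `c(12, 36)` h.
#' @return list with `period` (h), `phase_angle` (radians; the cosine phase
#'   at the first point of the series), and `in_bounds` flag.
#' @export
fft_initial_period <- function(series, interval_h, period_bounds = c(12, 36)) {
  n <- length(series)
  .check(n >= 4, "need at least 4 timepoints")
  .check(interval_h > 0, "interval_h must be positive")
  span <- n * interval_h
  X <- stats::fft(series)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  power <- Mod(X[k + 1])^2
  periods <- span / k
  inb <- periods > period_bounds[1] & periods < period_bounds[2]
  if (!any(inb) || all(power[inb] <= 0)) {
    return(list(period = 24, phase_angle = 0, in_bounds = FALSE))
  }
  kpk <- k[inb][which.max(power[inb])]
  # quadratic peak interpolation over (kpk-1, kpk, kpk+1); power domain,
  # which stays put when the neighbours carry negligible power
  khat <- kpk
  if (kpk > 1 && kpk < kmax) {
    pw <- power[c(kpk - 1, kpk, kpk + 1)]
    den <- pw[1] - 2 * pw[2] + pw[3]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (pw[1] - pw[3]) / den
      khat <- kpk + max(-0.5, min(0.5, delta))
    }
  }
  period <- span / khat
  eps <- 1e-6
  period <- min(max(period, period_bounds[1] + eps), period_bounds[2] - eps)
  list(period = period, phase_angle = Arg(X[kpk + 1]), in_bounds = TRUE)
}

# internal: weighted linear solve of the cosine+trend model at fixed period.
# X columns: cos(wt), sin(wt), 1, t - tbar. SSE is computed from explicit
# residuals: the normal-equations shortcut cancels catastrophically near a
# perfect fit and would stall the period refinement at ~1e-6.
.cos_profile <- function(period, times, values, weights, td) {
  w <- 2 * pi / period
  X <- cbind(cos(w * times), sin(w * times), 1, td)
  A <- crossprod(X, X * weights)
  b <- crossprod(X * weights, values)
  coef <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(coef)) return(list(sse = Inf, coef = NULL))
  r <- values - as.numeric(X %*% coef)
  list(sse = sum(weights * r^2), coef = as.numeric(coef))
}

#' Pearson correlation between observed and model-predicted values
#'
#' The circadian oscillation correlation: an unweighted Pearson correlation
#' between observed (trend-removed) expression and the best-fit cosine
#' prediction. Undefined (NA) when either vector has zero variance --
#' e.g. an amplitude-zero fit -- in which case the gene is treated as
#' arrhythmic downstream.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or NA if undefined.
#' @export
oscillation_correlation <- function(observed, predicted) {
  .check(length(observed) == length(predicted), "length mismatch")
  .check(length(observed) >= 3, "need at least 3 points")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  stats::cor(observed, predicted)
}

#' Fit the cosine oscillation model to one gene
#'
#' Model: `value = amplitude * cos(2*pi/period * time - 2*pi/24 * phase24)
#' + constant + slope * (time - mean time)`, minimizing the weighted sum of
#' squared errors subject to amplitude >= 0, period in
#' `(period_min, period_max)`, phase24 in `[0, 24)`. The trend is estimated
#' jointly with the oscillation (sequential detrending feeds only the FFT
#' initialization), by variable projection: at any candidate period the
#' remaining parameters are an exact weighted linear solve, and the period
#' is located on a coarse grid seeded with the FFT estimate and refined by
#' golden-section search. Standard errors come from the weighted Jacobian
#' at the optimum with `df = n - 4`.
#'
#' @param times sampling times in hours (>= 5 observations).
#' @param values expression values, typically log2(CPM).
#' @param weights positive observation weights (default all 1).
#' @param settings a [fit_settings()] object.
#' @return one-row data.frame with columns `gene` (NA here; filled by
#'   [fit_all()]), `amplitude`, `amp_se`, `period`, `period_se`, `phase24`,
#'   `phase24_se`, `constant`, `const_se`, `trend_slope`, `df`,
#'   `correlation`, `p_rhythm`, `sse`, `sse0`, `converged`, `at_bound`.
#' @export
#' @examples
#' t <- rep(seq(24, 68, by = 4), each = 2)
#' y <- 2 * cos(2 * pi / 24 * t - 2 * pi / 24 * 6) + 10
#' fit_cos(t, y)[, c("amplitude", "period", "phase24", "constant")]
fit_cos <- function(times, values, weights = NULL,
                    settings = fit_settings()) {
  n <- length(times)
  .check(n >= 5, "need at least 5 observations (df >= 1)")
  .check(length(values) == n, "times and values differ in length")
  if (is.null(weights) || !settings$use_weights) weights <- rep(1, n)
  .check(length(weights) == n && all(weights > 0),
         "weights must be positive and match length")
  fail <- data.frame(gene = NA_character_, amplitude = NA_real_,
                     amp_se = NA_real_, period = NA_real_,
                     period_se = NA_real_, phase24 = NA_real_,
                     phase24_se = NA_real_, constant = NA_real_,
                     const_se = NA_real_, trend_slope = NA_real_,
                     df = n - 4, correlation = NA_real_,
                     p_rhythm = NA_real_, sse = NA_real_, sse0 = NA_real_,
                     converged = FALSE, at_bound = FALSE,
                     stringsAsFactors = FALSE)
  if (!all(is.finite(values))) return(fail)

  tbar <- .wmean(times, weights)
  td <- times - tbar

  # null (trend + constant only) model
  dt0 <- detrend(times, values, weights)
  sse0 <- sum(weights * dt0$residuals^2)

  # FFT initialization on per-timepoint means of the detrended residuals
  p_fft <- NULL
  ut <- sort(unique(times))
  if (length(ut) >= 4) {
    steps <- diff(ut)
    if (max(steps) - min(steps) < 1e-8) {
      means <- vapply(ut, function(u) mean(dt0$residuals[times == u]),
                      numeric(1))
      p_fft <- fft_initial_period(means, steps[1],
                                  c(settings$period_min,
                                    settings$period_max))$period
    }
  }

  eps <- 1e-7
  grid <- seq(settings$period_min + settings$grid_step / 2,
              settings$period_max - settings$grid_step / 2,
              by = settings$grid_step)
  cand <- unique(c(grid, p_fft))
  sses <- vapply(cand, function(p)
    .cos_profile(p, times, values, weights, td)$sse, numeric(1))
  if (!any(is.finite(sses))) return(fail)
  best <- cand[which.min(sses)]

  lo <- max(best - settings$grid_step, settings$period_min + eps)
  hi <- min(best + settings$grid_step, settings$period_max - eps)
  opt <- stats::optimize(function(p)
    .cos_profile(p, times, values, weights, td)$sse,
    interval = c(lo, hi), tol = settings$tol)
  period <- opt$minimum
  if (opt$objective > min(sses)) period <- best  # refinement never worsens
  prof <- .cos_profile(period, times, values, weights, td)
  if (is.null(prof$coef) || !all(is.finite(prof$coef))) return(fail)

  a <- prof$coef[1]; b <- prof$coef[2]
  constant <- prof$coef[3]; slope <- prof$coef[4]
  amplitude <- sqrt(a^2 + b^2)
  psi <- atan2(b, a)
  phase24 <- wrap24(24 * psi / (2 * pi))
  sse <- prof$sse

  # Gauss-Newton polish of (A, P, phi, C, s) to machine precision;
  # steps that leave the period bounds or increase the SSE are rejected
  par <- c(amplitude, period, phase24, constant, slope)
  model_of <- function(p) {
    arg <- 2 * pi * times / p[2] - 2 * pi * p[3] / 24
    list(f = p[1] * cos(arg) + p[4] + p[5] * td, arg = arg)
  }
  sse_of <- function(p) {
    r <- values - model_of(p)$f
    sum(weights * r^2)
  }
  if (amplitude > 1e-12) {
    for (it in 1:20) {
      md <- model_of(par)
      r <- values - md$f
      J <- cbind(cos(md$arg),
                 par[1] * sin(md$arg) * 2 * pi * times / par[2]^2,
                 par[1] * sin(md$arg) * 2 * pi / 24,
                 1, td)
      step <- tryCatch(solve(crossprod(J, J * weights),
                             crossprod(J * weights, r)),
                       error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      improved <- FALSE
      for (h in c(1, 0.5, 0.25)) {
        trial <- par + h * as.numeric(step)
        if (trial[2] <= settings$period_min ||
            trial[2] >= settings$period_max) next
        s_new <- sse_of(trial)
        if (s_new <= sse) {
          improved <- s_new < sse * (1 - 1e-14) - 1e-300
          par <- trial
          sse <- s_new
          break
        }
      }
      if (!improved) break
    }
    if (par[1] < 0) {  # re-express negative amplitude
      par[1] <- -par[1]
      par[3] <- par[3] + 12
    }
    amplitude <- par[1]; period <- par[2]
    phase24 <- wrap24(par[3]); constant <- par[4]; slope <- par[5]
  }
  at_bound <- (period - settings$period_min < 1e-6) ||
              (settings$period_max - period < 1e-6)

  # standard errors from the weighted Jacobian of
  # f(A, P, phi, C, s) at the optimum; df = n - 4 by convention
  arg <- 2 * pi * times / period - 2 * pi * phase24 / 24
  J <- cbind(cos(arg),
             amplitude * sin(arg) * 2 * pi * times / period^2,
             amplitude * sin(arg) * 2 * pi / 24,
             1, td)
  dfree <- n - 4
  sigma2 <- sse / dfree
  covm <- tryCatch(solve(crossprod(J * sqrt(weights))) * sigma2,
                   error = function(e) NULL)
  ses <- if (is.null(covm)) rep(NA_real_, 5) else sqrt(pmax(diag(covm), 0))

  pred_cos <- amplitude * cos(arg)
  corr <- oscillation_correlation(values - slope * td, pred_cos)
  Fstat <- if (sse > 0) ((sse0 - sse) / 3) / (sse / dfree) else Inf
  p_rhythm <- if (is.finite(Fstat)) {
    stats::pf(Fstat, 3, dfree, lower.tail = FALSE)
  } else 0

  data.frame(gene = NA_character_, amplitude = amplitude, amp_se = ses[1],
             period = period, period_se = ses[2], phase24 = phase24,
             phase24_se = ses[3], constant = constant, const_se = ses[4],
             trend_slope = slope, df = dfree, correlation = corr,
             p_rhythm = p_rhythm, sse = sse, sse0 = sse0, converged = TRUE,
             at_bound = at_bound, stringsAsFactors = FALSE)
}

#' Oscillation F-test p-value
#'
#' Compares the cosine model against the trend-only model on the same
#' weighted observations: `F = ((SSE0 - SSE1)/3) / (SSE1/(n-4))`. A perfect
#' fit gives p -> 0; an amplitude-zero fit gives F = 0, p = 1. With
#' `null = NULL` the nominal `F(3, n-4)` tail is used; because the period
#' is itself searched over a band, the nominal reference is
#' anti-conservative under the null, and a [null_calibration()] object
#' should be supplied (or [fit_all()]'s `calibrate = TRUE` used) whenever
#' calibrated p-values matter.
#'
#' @param fit a one-row fit as returned by [fit_cos()].
#' @param n_obs number of observations (default `fit$df + 4`).
#' @param null optional [null_calibration()] object.
#' @return p-value, or NA for a non-converged fit or df <= 0.
#' @export
rhythm_pvalue <- function(fit, n_obs = fit$df + 4, null = NULL) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  dfree <- n_obs - 4
  if (dfree <= 0) return(NA_real_)
  if (fit$sse <= 0) return(0)
  if (!is.null(null)) return(calibrated_pvalue(fit, null))
  Fstat <- ((fit$sse0 - fit$sse) / 3) / (fit$sse / dfree)
  stats::pf(Fstat, 3, dfree, lower.tail = FALSE)
}

#' Predict expression from a fitted cosine model
#'
#' @param fit one row of a fits table.
#' @param times hours at which to predict.
#' @param include_trend include the fitted linear trend (default TRUE).
#' @param tbar time origin of the trend term; default the mean of `times`.
#' @return numeric vector of predicted values.
#' @export
predict_cos <- function(fit, times, include_trend = TRUE, tbar = mean(times)) {
  out <- fit$amplitude *
    cos(2 * pi * times / fit$period - 2 * pi * fit$phase24 / 24) +
    fit$constant
  if (include_trend && is.finite(fit$trend_slope)) {
    out <- out + fit$trend_slope * (times - tbar)
  }
  out
}

#' Fit the cosine model to every gene of a normalized matrix
#'
#' One [fit_cos()] per kept gene, using each gene's observation weights.
#' Per-gene failures are recorded as non-converged rows and never abort the
#' run; gene order is preserved and results are independent of it.
#'
#' @param norm a `normalized_matrix` (with weights; equal weights are used
#'   if the slot is empty).
#' @param settings a [fit_settings()] object.
#' @param calibrate recalibrate `p_rhythm` against the design's Monte Carlo
#'   null (see [null_calibration()]); default TRUE.
#' @param verbose log progress every 500 genes.
#' @return data.frame of fits, one row per gene (columns as [fit_cos()]).
#' @export
fit_all <- function(norm, settings = fit_settings(), calibrate = TRUE,
                    verbose = FALSE) {
  .check(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
  y <- norm$log2cpm
  w <- norm$weights
  if (is.null(w)) w <- matrix(1, nrow(y), ncol(y))
  times <- norm$samples$zt_hour
  rows <- vector("list", nrow(y))
  for (i in seq_len(nrow(y))) {
    rows[[i]] <- tryCatch(fit_cos(times, y[i, ], w[i, ], settings),
                          error = function(e)
                            fit_cos(times, rep(NA_real_, length(times)),
                                    NULL, settings))
    rows[[i]]$gene <- rownames(y)[i]
    if (verbose && i %% 500 == 0) {
      message(sprintf("fit %d/%d genes", i, nrow(y)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (calibrate) out <- calibrate_pvalues(out, times, settings)
  out
}
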