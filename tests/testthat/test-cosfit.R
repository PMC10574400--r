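test_that("detrending removes exact lines and matches the normal-equations oracle", {
  t <- tt_default()
  w <- runif(length(t), 0.5, 2)
  dt <- detrend(t, 2 * t + 5, w)
  expect_equal(dt$slope, 2, tolerance = 1e-10)
  expect_equal(dt$intercept, 5, tolerance = 1e-8)
  expect_lt(max(abs(dt$residuals)), 1e-9)

  set.seed(31)
  y <- rnorm(length(t))
  dt2 <- detrend(t, y, w)
  o <- oracle_wls_line(t, y, w)
  expect_equal(dt2$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(dt2$residuals, y - o["intercept"] - o["slope"] * t,
               ignore_attr = TRUE, tolerance = 1e-10)
  # weighted orthogonality post-conditions
  expect_lt(abs(sum(w * dt2$residuals)), 1e-8)
  expect_lt(abs(sum(w * dt2$residuals * t)), 1e-6)

  expect_error(detrend(rep(1, 5), rnorm(5)), "constant time")
  expect_error(detrend(1:2, 1:2), "3 points")
})

test_that("FFT initialization finds the dominant in-bounds frequency", {
  tp <- seq(24, 68, by = 4)
  s24 <- make_cos(tp, 1, 24, 3)
  init <- fft_initial_period(s24, 4)
  expect_true(init$in_bounds)
  expect_gt(init$period, 20)
  expect_lt(init$period, 28)

  # two components: the stronger one's frequency bin wins (24 h beats 16 h;
  # the quadratic refinement is only an initializer, so assert bin choice)
  s2 <- make_cos(tp, 2, 24, 3) + make_cos(tp, 0.5, 16, 8)
  init2 <- fft_initial_period(s2, 4)
  expect_lt(abs(init2$period - 24), abs(init2$period - 16))

  # white noise still yields an in-bounds proposal
  set.seed(32)
  initn <- fft_initial_period(rnorm(12), 4)
  expect_gt(initn$period, 12)
  expect_lt(initn$period, 36)

  # flat series falls back to 24 h
  expect_false(fft_initial_period(rep(0, 12), 4)$in_bounds)
})

test_that("noiseless curves are recovered exactly, including the peak-time identity", {
  t <- tt_default()
  f <- fit_cos(t, make_cos(t, 2, 24, 6, 10))
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  expect_equal(f$period, 24, tolerance = 1e-6)
  expect_equal(f$phase24, 6, tolerance = 1e-6)
  expect_equal(f$constant, 10, tolerance = 1e-6)
  expect_equal(f$correlation, 1, tolerance = 1e-9)
  expect_true(f$converged)
  expect_false(f$at_bound)
  expect_equal(f$df, length(t) - 4)

  # peak where the cosine argument vanishes: time = period * phase24 / 24
  tg <- seq(0, 24, by = 1e-4)
  pk <- tg[which.max(predict_cos(f, tg, include_trend = FALSE))]
  expect_equal(pk %% 24, 6, tolerance = 1e-3)

  # a linear trend on top is absorbed without biasing the oscillation
  f2 <- fit_cos(t, make_cos(t, 1.5, 25.3, 17.2, 7) + 0.02 * t)
  expect_equal(f2$amplitude, 1.5, tolerance = 1e-6)
  expect_equal(f2$period, 25.3, tolerance = 1e-6)
  expect_equal(f2$phase24, 17.2, tolerance = 1e-6)
  expect_equal(f2$trend_slope, 0.02, tolerance = 1e-6)
})

test_that("the profiled fit never loses to a dense grid-search oracle", {
  t <- tt_default()
  set.seed(33)
  for (i in 1:10) {
    y <- make_cos(t, runif(1, 0.5, 2), runif(1, 16, 30), runif(1, 0, 24),
                  5) + rnorm(length(t), sd = 0.5)
    w <- runif(length(t), 0.5, 2)
    f <- fit_cos(t, y, w)
    o <- oracle_grid_sse(t, y, w, period_step = 0.05, phase_step = 0.2)
    expect_lte(f$sse, o + 1e-6)
  }
})

test_that("fits are equivariant to time shifts and amplitude scaling", {
  t <- tt_default()
  set.seed(34)
  for (i in 1:8) {
    y <- make_cos(t, runif(1, 1, 2), runif(1, 20, 28), runif(1, 0, 24), 5) +
      rnorm(length(t), sd = 0.2)
    f <- fit_cos(t, y)

    delta <- runif(1, 1, 10)
    fs <- fit_cos(t + delta, y)
    expect_equal(fs$period, f$period, tolerance = 1e-6)
    expect_equal(fs$amplitude, f$amplitude, tolerance = 1e-6)
    expect_equal(wrap_phase_diff(fs$phase24 -
                                 (f$phase24 + 24 * delta / f$period)), 0,
                 tolerance = 1e-5)

    cmul <- runif(1, 0.5, 3)
    fc <- fit_cos(t, cmul * y)
    expect_equal(fc$amplitude, cmul * f$amplitude, tolerance = 1e-6)
    expect_equal(fc$constant, cmul * f$constant, tolerance = 1e-6)
    expect_equal(fc$period, f$period, tolerance = 1e-6)
    expect_equal(fc$phase24, f$phase24, tolerance = 1e-5)
    expect_equal(fc$correlation, f$correlation, tolerance = 1e-9)
  }
})

test_that("the oscillation correlation is plain Pearson with degenerate cases as NA", {
  set.seed(35)
  x <- rnorm(24); y <- rnorm(24)
  r <- oscillation_correlation(x, y)
  # hand-coded Pearson formula
  rr <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rr, tolerance = 1e-12)
  expect_true(is.na(oscillation_correlation(x, rep(1, 24))))
  expect_error(oscillation_correlation(1:2, 1:2), "3 points")
})

test_that("the rhythm p-value spans its limits", {
  t <- tt_default()
  # perfect fit: p -> 0
  fp <- fit_cos(t, make_cos(t, 2, 24, 6, 10))
  expect_equal(fp$p_rhythm, 0)
  expect_equal(rhythm_pvalue(fp), 0)
  # amplitude-zero fit (SSE1 = SSE0): F = 0, p = 1
  f0 <- fp
  f0$sse <- f0$sse0 <- 3.3
  expect_equal(rhythm_pvalue(f0), 1)
  # non-converged: NA
  fn <- fp; fn$converged <- FALSE
  expect_true(is.na(rhythm_pvalue(fn)))
})

test_that("batch fitting equals per-gene fitting, independent of order", {
  d <- make_design()
  t <- d$samples$zt_hour
  set.seed(36)
  n_g <- 30
  y <- t(vapply(seq_len(n_g), function(i)
    make_cos(t, runif(1, 0.5, 2), runif(1, 20, 28), runif(1, 0, 24),
             runif(1, 4, 10)) + rnorm(length(t), sd = 0.3),
    numeric(length(t))))
  dimnames(y) <- list(sprintf("g%03d", seq_len(n_g)), d$samples$sample_id)
  w <- matrix(runif(length(y), 0.5, 2), nrow = n_g, dimnames = dimnames(y))
  norm <- as_norm(y, d, w)

  fits <- fit_all(norm, calibrate = FALSE)
  expect_equal(nrow(fits), n_g)
  expect_equal(fits$gene, rownames(y))

  # batch row i == single fit of gene i
  f7 <- fit_cos(t, y[7, ], w[7, ])
  expect_equal(fits$period[7], f7$period)
  expect_equal(fits$phase24[7], f7$phase24)
  expect_equal(fits$sse[7], f7$sse)

  # permuting genes permutes rows, nothing else
  perm <- sample(n_g)
  norm_p <- as_norm(y[perm, ], d, w[perm, ])
  fits_p <- fit_all(norm_p, calibrate = FALSE)
  expect_equal(fits_p[match(fits$gene, fits_p$gene), -1], fits[, -1],
               ignore_attr = TRUE)

  # rerun: identical
  expect_identical(fit_all(norm, calibrate = FALSE), fits)

  # a failing gene yields a non-converged row, not an abort
  y2 <- y; y2[3, ] <- NA
  fits2 <- fit_all(as_norm(y2, d, w), calibrate = FALSE)
  expect_false(fits2$converged[3])
  expect_true(all(fits2$converged[-3]))
})

test_that("null calibration makes white-noise p-values approximately uniform", {
  d <- make_design()
  t <- d$samples$zt_hour
  set.seed(37)
  n_g <- 300
  y <- matrix(rnorm(n_g * length(t)), nrow = n_g,
              dimnames = list(sprintf("n%03d", seq_len(n_g)),
                              d$samples$sample_id))
  fits <- fit_all(as_norm(y, d), calibrate = TRUE)
  ks <- suppressWarnings(ks.test(fits$p_rhythm, "punif"))
  expect_lt(unname(ks$statistic), 0.1)

  # nominal p-values are anti-conservative by comparison
  fits_nom <- fit_all(as_norm(y, d), calibrate = FALSE)
  expect_gt(mean(fits_nom$p_rhythm < 0.05), 0.10)

  # the calibration itself is cached and deterministic
  n1 <- null_calibration(t)
  n2 <- null_calibration(t)
  expect_identical(n1, n2)
})
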