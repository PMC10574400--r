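test_that("expression filter matches a per-gene brute-force application of its rule", {
  d <- make_design()
  ds <- simulate_dataset(d, n_genes = 1000, seed = 21)
  # mix in hard cases: all-zero and uniformly high genes
  counts <- ds$counts
  counts["g0001", ] <- 0
  counts["g0002", ] <- 5000
  tc <- timecourse(counts, d$samples)

  kept <- filter_expressed(tc, min_count = 10, min_samples_frac = 1 / 12,
                           min_total = 15)
  expect_false("g0001" %in% kept)
  expect_true("g0002" %in% kept)

  # independent re-application of the stated rule, gene by gene
  lib <- colSums(counts)
  cutoff <- 10 / median(lib) * 1e6
  k <- ceiling(1 / 12 * ncol(counts))
  oracle <- character(0)
  for (g in rownames(counts)) {
    cpm_g <- counts[g, ] / lib * 1e6
    if (sum(cpm_g >= cutoff) >= k && sum(counts[g, ]) > 15) {
      oracle <- c(oracle, g)
    }
  }
  expect_identical(kept, oracle)

  # monotone: raising min_count never adds genes
  kept_hi <- filter_expressed(tc, min_count = 50)
  expect_true(all(kept_hi %in% kept))

  tc0 <- timecourse(matrix(0, 2, 24, dimnames = list(c("a", "b"),
                                                     d$samples$sample_id)),
                    d$samples)
  expect_warning(k0 <- filter_expressed(tc0), "no genes")
  expect_length(k0, 0)
})

test_that("scaling factors obey symmetry, composition invariance, and the trimmed-mean definition", {
  d <- make_design(6, 4, 24, 2)
  set.seed(22)
  base <- matrix(rnbinom(500 * 12, mu = 200, size = 5), 500, 12,
                 dimnames = list(sprintf("g%03d", 1:500), d$samples$sample_id))

  ident <- timecourse(matrix(base[, 1], 500, 12,
                             dimnames = dimnames(base)), d$samples)
  expect_equal(unname(scaling_factors(ident)), rep(1, 12), tolerance = 1e-12)

  # doubling a sample's counts leaves composition, hence its factor, alone
  doubled <- base
  doubled[, 3] <- doubled[, 3] * 2
  f <- scaling_factors(timecourse(doubled, d$samples))
  f0 <- scaling_factors(timecourse(base, d$samples))
  expect_equal(unname(f[3] / f0[3]), 1, tolerance = 0.02)

  # geometric mean one
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)

  # against a literal step-by-step trimmed-mean oracle (shared reference)
  tcb <- timecourse(base, d$samples)
  fb <- scaling_factors(tcb, ref = "ZT32_r1")
  raw <- vapply(colnames(base), function(s)
    oracle_tmm_factor(base[, s], base[, "ZT32_r1"]), numeric(1))
  expect_equal(unname(fb), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)

  bad <- base; bad[, 5] <- 0
  expect_error(scaling_factors(timecourse(bad, d$samples)), "ZT32_r1")
})

test_that("log2(CPM) has the closed form, monotonicity and common-scale invariance", {
  d <- make_design(6, 4, 24, 2)
  counts <- matrix(1000, 2, 12,
                   dimnames = list(c("a", "b"), d$samples$sample_id))
  counts["b", ] <- 1e6 - 1000
  tc <- timecourse(counts, d$samples)
  norm <- log2_cpm(tc, factors = rep(1, 12), prior_count = 1e-9)
  expect_equal(unname(norm$log2cpm["a", 1]), log2(1000), tolerance = 1e-6)

  # monotone in each count
  counts2 <- counts; counts2["a", 1] <- 1001
  norm2 <- log2_cpm(timecourse(counts2, d$samples), rep(1, 12))
  norm1 <- log2_cpm(tc, rep(1, 12))
  expect_gt(norm2$log2cpm["a", 1], norm1$log2cpm["a", 1])

  # rescaling all counts by a common factor changes log2cpm negligibly
  set.seed(23)
  m <- matrix(rnbinom(200 * 12, mu = 100, size = 5) + 1, 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), d$samples$sample_id))
  n1 <- log2_cpm(timecourse(m, d$samples))
  n4 <- log2_cpm(timecourse(m * 4, d$samples))
  expect_lt(max(abs(n1$log2cpm - n4$log2cpm)), 1e-9)

  # zero counts give one constant per sample set by the prior
  z <- matrix(0, 3, 12, dimnames = list(c("a", "b", "c"),
                                        d$samples$sample_id))
  z[3, ] <- 100  # keep libraries non-zero
  nz <- log2_cpm(timecourse(z, d$samples))
  expect_equal(nz$log2cpm["a", ], nz$log2cpm["b", ])
})

test_that("precision weights are positive, mean-one, and track designed heteroscedasticity", {
  d <- make_design()
  t <- d$samples$zt_hour
  set.seed(24)
  n_g <- 2000
  curves <- t(vapply(seq_len(n_g), function(i)
    make_cos(t, runif(1, 0.5, 2), 24, runif(1, 0, 24), runif(1, 4, 10)),
    numeric(length(t))))
  rownames(curves) <- sprintf("g%04d", seq_len(n_g))
  colnames(curves) <- d$samples$sample_id

  # homoscedastic data: mean-variance weights approximately constant
  y <- curves + matrix(rnorm(length(curves), sd = 0.3), nrow = n_g)
  norm <- as_norm(y, d)
  w <- estimate_weights(norm, mode = "mean_variance")$weights
  expect_true(all(w > 0))
  expect_lt(sd(w) / mean(w), 0.2)

  # equal mode: exactly 1
  we <- estimate_weights(norm, mode = "equal")$weights
  expect_true(all(we == 1))

  # a sample with doubled noise gets the smallest quality factor
  y2 <- curves + matrix(rnorm(length(curves), sd = 0.3), nrow = n_g)
  y2[, 7] <- curves[, 7] + rnorm(n_g, sd = 0.6)
  wq <- estimate_weights(as_norm(y2, d), mode = "per_sample_quality")$weights
  expect_equal(unname(which.min(colMeans(wq))), 7)
  expect_equal(mean(wq), 1, tolerance = 1e-9)

  # external mode passes matrices through
  wx <- matrix(2, n_g, ncol(y), dimnames = dimnames(y))
  expect_equal(estimate_weights(norm, mode = "external",
                                external = wx)$weights, wx)
})

test_that("sample correlations are symmetric and strongest 24 h apart for rhythmic data", {
  d <- make_design()
  t <- d$samples$zt_hour
  set.seed(25)
  n_g <- 500
  y <- t(vapply(seq_len(n_g), function(i)
    make_cos(t, runif(1, 1, 2), 24, runif(1, 0, 24), runif(1, 4, 10)),
    numeric(length(t)))) +
    matrix(rnorm(n_g * length(t), sd = 0.3), nrow = n_g)
  rownames(y) <- sprintf("g%04d", seq_len(n_g))
  colnames(y) <- d$samples$sample_id
  cc <- sample_correlation(as_norm(y, d))

  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, ncol(y)))
  expect_true(all(cc >= -1 & cc <= 1))

  dt <- abs(outer(t, t, "-"))
  off <- upper.tri(cc)
  expect_gt(mean(cc[off & dt == 24]), mean(cc[off & dt == 12]))

  # duplicated columns correlate exactly
  y2 <- y; y2[, 2] <- y2[, 1]
  cc2 <- sample_correlation(as_norm(y2, d))
  expect_equal(unname(cc2[1, 2]), 1)

  # zero-variance sample reported as missing
  y3 <- y; y3[, 4] <- 1
  cc3 <- sample_correlation(as_norm(y3, d))
  expect_true(all(is.na(cc3[4, -4])))
})
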