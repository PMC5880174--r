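test_that("fBm generator enforces its parameter domain", {
  expect_error(fbm_spec(H = 1.2, n = 1024), "inside \\(0, 1\\)")
  expect_error(fbm_spec(H = 0, n = 1024), "inside \\(0, 1\\)")
  expect_error(fbm_spec(H = 0.5, n = 1000), "power of two")
  expect_error(fbm_spec(H = 0.5, n = 128), "power of two")
})

test_that("H = 1/2 increments are white and unit variance", {
  tr <- gen_fbm(fbm_spec(0.5, 2^14, seed = 4, output = "increments"))
  x <- tr$values
  n <- length(x)
  for (lag in 1:10) {
    r <- cor(x[1:(n - lag)], x[(1 + lag):n])
    expect_lt(abs(r), 4 / sqrt(n))
  }
  expect_equal(var(x), 1, tolerance = 0.05)
})

test_that("fGn matches the closed-form covariance it embeds", {
  H <- 1/3
  tr <- gen_fbm(fbm_spec(H, 2^16, seed = 8, output = "path"))
  x <- tr$values
  # variance of k-lag increments of the path is the closed-form fBm
  # structure function ~ k^(2H); the embedded acf gives the exact values
  ks <- c(1, 2, 4, 8, 16, 32)
  v <- vapply(ks, function(k) var(diff(x, lag = k)), numeric(1))
  sl <- unname(coef(lm(log(v) ~ log(ks)))[2])
  expect_equal(sl, 2 * H, tolerance = 0.05)
  # lag-1 increment autocovariance: exact fGn value
  inc <- diff(x)
  expect_equal(mean(inc[-1] * inc[-length(inc)]),
               oracle_fgn_acf(H, 1), tolerance = 0.02)
})

test_that("generators are pure functions of their spec (seed determinism)", {
  s <- fbm_spec(0.7, 2^10, seed = 42)
  expect_identical(gen_fbm(s)$values, gen_fbm(s)$values)
  cs <- cascade_spec(-0.3, 0.04, 10, mode = "multiplicative", seed = 9)
  expect_identical(gen_cascade_signal(cs)$values, gen_cascade_signal(cs)$values)
  es <- egm_spec(duration = 10, seed = 3)
  expect_identical(gen_surrogate_egm(es)$values, gen_surrogate_egm(es)$values)
  # the generators must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(gen_fbm(s)); b <- runif(1)
  expect_identical(a, b)
})

test_that("degenerate cascade (c2 = 0) has deterministic magnitudes per level", {
  tr <- gen_cascade_signal(cascade_spec(-0.34, 0, 10, seed = 2))
  om <- attr(tr, "omega")
  for (j in c(3, 6, 9)) {
    expect_equal(var(om[[j]]), 0)
    expect_equal(om[[j]][1], j * 0.34 * log(2), tolerance = 1e-12)
  }
})

test_that("multiplicative-mode omega covariance follows the ancestry path", {
  s2 <- 0.06 * log(2)
  tr <- gen_cascade_signal(cascade_spec(-0.3, 0.06, 12, mode = "multiplicative",
                                        seed = 7))
  om <- attr(tr, "omega")
  expect_equal(attr(tr, "level_var"), s2, tolerance = 1e-12)
  # brute force over the stored tree: cell at depth j vs ancestor at depth d
  j <- 12L
  for (d in c(4L, 7L, 10L)) {
    anc <- rep(om[[d]], each = 2L^(j - d))
    emp <- mean(om[[j]] * anc) - mean(om[[j]]) * mean(anc)
    theo <- d * s2
    se <- 4 * theo / sqrt(2^d)     # rough large-sample error band
    expect_lt(abs(emp - theo), se + 0.05)
  }
})

test_that("uncorrelated-mode omega has no cross-cell covariance", {
  tr <- gen_cascade_signal(cascade_spec(-0.3, 0.06, 12, mode = "uncorrelated",
                                        seed = 7))
  om <- attr(tr, "omega")
  x <- om[[12]]
  n <- length(x)
  r <- cor(x[-1], x[-n])
  expect_lt(abs(r), 4 / sqrt(n))
  # and no covariance with the (would-be) ancestor level
  anc <- rep(om[[6]], each = 2^6)
  expect_lt(abs(cor(x, anc)), 4 / sqrt(2^6))
})

test_that("the two cascade modes share their one-point statistics", {
  spm <- cascade_spec(-0.34, 0.05, 12, mode = "multiplicative", seed = 3)
  spu <- cascade_spec(-0.34, 0.05, 12, mode = "uncorrelated", seed = 3)
  om_m <- attr(gen_cascade_signal(spm), "omega")
  om_u <- attr(gen_cascade_signal(spu), "omega")
  for (j in c(8, 10, 12)) {
    n <- 2^j
    mu <- j * 0.34 * log(2); v <- j * 0.05 * log(2)
    # multiplicative cells are correlated: conservative 3-se bands use the
    # effective sample size of the shallowest independent level
    expect_lt(abs(mean(om_m[[j]]) - mu), 3 * sqrt(v / 2^4) + 0.05)
    expect_lt(abs(mean(om_u[[j]]) - mu), 3 * sqrt(v / n))
    expect_lt(abs(var(om_m[[j]]) - v), 0.5 * v)
    expect_lt(abs(var(om_u[[j]]) - v), 0.2 * v)
  }
})

test_that("cascade spec validation", {
  expect_error(cascade_spec(-0.3, -0.01, 10), "c2_target")
  expect_error(cascade_spec(-0.3, 0.05, 6), "n_octaves")
  expect_error(cascade_spec(-0.3, 0.05, 10, mode = "banana"), "arg")
})

test_that("fixtures are the advertised deterministic signals", {
  d <- gen_fixture(fixture_spec("delta", n = 2^14, location = 2^13))
  expect_equal(sum(d$values != 0), 1L)
  expect_equal(d$values[2^13 + 1], 1)

  r <- gen_fixture(fixture_spec("ramp", n = 256, amplitude = 3, dt = 0.1))
  expect_equal(diff(r$values), rep(3 * 0.1, 255), tolerance = 1e-12)

  s <- gen_fixture(fixture_spec("sine", n = 1000, period = 125))
  expect_identical(s$values[1:500], s$values[126:625])

  expect_error(gen_fixture(fixture_spec("delta", n = 100, location = 100)),
               "location")
  expect_error(fixture_spec("sawtooth", n = 100), "unknown fixture kind")
})

test_that("surrogate electrogram has the prescribed beat statistics", {
  spec <- egm_spec(duration = 60, dt = 1e-3, mean_rate = 5, rate_cv = 0.2,
                   deflection_width = 0.02, baseline_noise_sd = 0, seed = 12)
  tr <- gen_surrogate_egm(spec)
  # count deflections as peaks above half max
  x <- tr$values
  thr <- max(x) / 2
  up <- which(x[-1] > thr & x[-length(x)] <= thr)
  expect_lt(abs(length(up) - 300), 4 * sqrt(300))
  # noiseless trace is exactly the sum of placed templates: samples far from
  # any beat are exactly zero
  beats <- attr(tr, "beat_times")
  tt <- trace_times(tr)
  far <- vapply(tt, function(t0) min(abs(t0 - beats)) > 0.05, logical(1))
  expect_true(all(x[far] == 0))
  expect_error(egm_spec(duration = 60, mean_rate = 5, deflection_width = 0.3),
               "deflection_width")
  expect_error(egm_spec(duration = 1, mean_rate = 5), "beats")

  # multifractal log-amplitude modulation produces variable beat amplitudes
  mod <- egm_spec(duration = 60, mean_rate = 5, seed = 12,
                  amplitude_magnitude = cascade_spec(-0.3, 0.06, 10, seed = 4))
  tr2 <- gen_surrogate_egm(mod)
  amp <- attr(tr2, "beat_amp")
  expect_gt(sd(amp), 0.05)
  expect_true(all(amp > 0))
  expect_identical(gen_surrogate_egm(mod)$values, tr2$values)
})

test_that("closed-form tau matches the analytic spectra", {
  fb <- fbm_spec(0.5, 1024)
  expect_equal(closed_form_tau(fb, 2), 0)
  expect_equal(closed_form_tau(fb, c(0, 1)), c(-1, -0.5))
  cs <- cascade_spec(-0.34, 0.053, 10)
  expect_equal(closed_form_tau(cs, 0), -1)
  # tau(2) = -(c0 + ... ) identity with c0 = 1: tau(2) = -1 + 2 c1 - 2 c2
  expect_equal(closed_form_tau(cs, 2), -1 + 2 * (-0.34) - 2 * 0.053)
  expect_error(closed_form_tau(cs, c(1, Inf)), "finite")
})
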