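# shared fixtures: delta skeleton (analytic) and fBm path skeleton (monofractal)
sp_delta_n <- 2^14
sp_delta_skel <- build_skeleton(
  cwt_transform(gen_fixture(fixture_spec("delta", n = sp_delta_n,
                                         location = sp_delta_n / 2)),
                scale_grid(2^4, 2^9, 8), order = 2))
sp_fbm_skel <- build_skeleton(
  cwt_transform(gen_fbm(fbm_spec(1/3, 2^16, seed = 5, output = "path")),
                scale_grid(2^4, 2^9, 8), order = 3))

test_that("partition identities hold exactly", {
  wn <- gen_fixture(fixture_spec("white_noise", n = 2^12, seed = 17))
  sk <- build_skeleton(cwt_transform(wn, scale_grid(2^4, 2^7, 8), order = 2))
  ens <- partition_functions(sk, q = c(-1, 0, 0.5, 2, 5))
  i0 <- which(ens$q == 0)
  # Z(0, a) = N_a exactly
  expect_equal(exp(ens$lnZ[i0, ]), as.numeric(ens$N_a), tolerance = 1e-12)
  # D(0, a) = -ln N_a
  expect_equal(ens$D_canon[i0, ], -log(ens$N_a), tolerance = 1e-12)
  # h(0, a) is the arithmetic mean magnitude (= C1(a))
  expect_equal(ens$h_canon[i0, ],
               vapply(ens$mags, function(m) mean(log(m)), numeric(1)),
               tolerance = 1e-12)
  # Boltzmann weights sum to one for every (q, a)
  for (s in seq_along(ens$scales)) {
    lnv <- log(ens$mags[[s]])
    for (k in seq_along(ens$q)) {
      w <- exp(ens$q[k] * lnv - ens$lnZ[k, s])
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
})

test_that("single delta-ridge line gives tau(q) = -q to machine precision", {
  # a lone maxima line carrying the impulse response kappa / a: by hand,
  # Z(q, a) = (kappa/a)^q, so tau(q) = -q and D(q) = 0 over any fit range
  scales <- 2^seq(4, 9, by = 0.25)
  kappa <- abs(eval_wavelet(2, 0))
  sk1 <- make_skeleton(matrix(kappa / scales, nrow = 1), scales)
  ens <- partition_functions(sk1, q = seq(-1, 5, 0.5))
  fit <- fit_scaling_exponents(ens, range(scales))
  expect_equal(fit$tau, -fit$q, tolerance = 1e-8)
  expect_equal(fit$D, rep(0, length(fit$q)), tolerance = 1e-10)
  # the real delta skeleton's central ridge reproduces the same law
  ridge <- line_exponent(sp_delta_skel, central_line(sp_delta_skel, sp_delta_n / 2))
  expect_equal(ridge$slope, -1, tolerance = 0.02)
})

test_that("exact power-law partition functions are fit to machine precision", {
  q <- seq(-1, 3, 0.5)
  a <- 2^seq(4, 8, by = 0.25)
  phi <- -1 + 0.4 * q - 0.03 * q^2
  fake <- structure(list(q = q, scales = a, lnZ = outer(phi, log(a)),
                         h_canon = outer(0.4 - 0.06 * q, log(a)),
                         D_canon = outer(-1 - 0.03 * q^2, log(a)),
                         N_a = rep(100L, length(a)), voices = 4,
                         value_mode = "value"),
                    class = "partition_ensemble")
  fit <- fit_scaling_exponents(fake, c(2^4, 2^8))
  expect_equal(fit$tau, phi, tolerance = 1e-10)
  expect_equal(fit$h, 0.4 - 0.06 * q, tolerance = 1e-10)
  expect_error(fit_scaling_exponents(fake, c(2, 2^9)), "beyond")
  expect_error(fit_scaling_exponents(fake, c(2^4, 2^4.2)), "fewer than 4")
})

test_that("monofractal fBm path recovers tau(q) = qH - 1 within 0.1", {
  ens <- partition_functions(sp_fbm_skel, q = seq(-1, 5, 0.25),
                             value_mode = "sup")
  fit <- fit_scaling_exponents(ens, c(2^5, 2^8))
  expect_lt(max(abs(fit$tau - (fit$q / 3 - 1))), 0.1)
  quad <- fit_quadratic_tau(fit)
  expect_lte(quad$c2, 0.02)          # monofractal: no intermittency
  expect_lt(abs(quad$c1 - 1/3), 0.05)
  expect_lt(abs(quad$c0 - 1), 0.05)
})

test_that("Legendre machinery matches closed forms", {
  # quadratic tau -> parabolic D(h), exactly
  c0 <- 1; c1 <- -0.34; c2 <- 0.053
  q <- seq(-2, 6, by = 0.05)
  tau <- -c0 + c1 * q - c2 * q^2 / 2
  leg <- legendre_transform(q, tau)
  interior <- 3:(length(q) - 2)
  expect_equal(leg$D[interior],
               quadratic_dh(leg$h[interior], c0, c1, c2), tolerance = 1e-3)
  expect_equal(max(quadratic_dh(seq(-1, 1, 1e-4), c0, c1, c2)), c0,
               tolerance = 1e-6)
  # monofractal tau -> the curve collapses onto the single point (H, 1)
  tau_m <- 0.3 * q - 1
  leg_m <- legendre_transform(q, tau_m)
  expect_equal(leg_m$h, rep(0.3, length(q)), tolerance = 1e-10)
  expect_equal(leg_m$D, rep(1, length(q)), tolerance = 1e-10)
})

test_that("canonical duality: D(h(q)) = q h(q) - tau(q) within errors", {
  ens <- partition_functions(sp_fbm_skel, q = seq(0, 3, 0.25),
                             value_mode = "sup")
  fit <- fit_scaling_exponents(ens, c(2^5, 2^8))
  resid <- fit$D - (fit$q * fit$h - fit$tau)
  band <- 2 * sqrt(fit$D_se^2 + (fit$q * fit$h_se)^2 + fit$tau_se^2)
  expect_true(all(abs(resid) <= band + 0.05))
})

test_that("quadratic tau fit is exact on noiseless input and guards c2 >= 0", {
  q <- seq(-1, 5, by = 0.25)
  fit <- list(q = q, tau = -1 + 0.5 * q - 0.025 * q^2)
  quad <- fit_quadratic_tau(fit)
  expect_equal(quad$c0, 1, tolerance = 1e-10)
  expect_equal(quad$c1, 0.5, tolerance = 1e-10)
  expect_equal(quad$c2, 0.05, tolerance = 1e-10)
  # convex tau (negative curvature coefficient) is clamped, raw kept
  fit2 <- list(q = q, tau = -1 + 0.5 * q + 0.01 * q^2)
  quad2 <- fit_quadratic_tau(fit2)
  expect_equal(quad2$c2, 0)
  expect_equal(quad2$c2_raw, -0.02, tolerance = 1e-10)
  expect_error(fit_quadratic_tau(list(q = 1:3, tau = c(1, 2, 3))), "5 q points")
  # cubic term recovered exactly when max_order = 3
  fit3 <- list(q = q, tau = -1 + 0.5 * q - 0.025 * q^2 + 0.002 * q^3)
  quad3 <- fit_quadratic_tau(fit3, max_order = 3L)
  expect_equal(quad3$c3, 0.012, tolerance = 1e-9)
  expect_equal(quad3$c1, 0.5, tolerance = 1e-9)
})

test_that("propagator collapse separates right and wrong kernels on fBm", {
  sk2 <- build_skeleton(
    cwt_transform(gen_fbm(fbm_spec(1/3, 2^16, seed = 5, output = "path")),
                  scale_grid(2^4, 2^9, 8), order = 2))
  sidx <- vapply(c(2^5, 2^7), function(a)
    which.min(abs(sk2$scales - a)), integer(1))
  d_ok <- pdf_collapse(sk2, propagator_model(1/3, 0), sidx)
  d_bad <- pdf_collapse(sk2, propagator_model(1/3 + 0.3, 0), sidx)
  expect_gt(d_bad$ks_dist, 3 * d_ok$ks_dist)
  # matched kernel lands near the two-half self-distance of the data
  m <- log(line_set_at_scale(sk2, sidx[1])$mag)
  self_d <- suppressWarnings(
    stats::ks.test(m[seq(1, length(m), 2)], m[seq(2, length(m), 2)])$statistic)
  expect_lt(d_ok$ks_dist, 3 * self_d + 0.05)
  expect_error(pdf_collapse(sk2, propagator_model(0.3, 0), sidx[1]),
               "2 scales")
  expect_error(propagator_model(0.3, -0.1), "c2")
})
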