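test_that("cumulants of crafted magnitude sets are exact", {
  scales <- 2^seq(4, 8, by = 0.5)
  # all magnitudes equal at each scale: C2 = C3 = 0 exactly, C1 = alpha ln a
  alpha <- -0.8
  mags <- matrix(rep(exp(alpha * log(scales)), each = 40), nrow = 40,
                 byrow = FALSE)
  sk <- make_skeleton(mags, scales)
  cc <- compute_magnitude_cumulants(sk)
  expect_equal(cc$C1, alpha * log(scales), tolerance = 1e-12)
  expect_equal(cc$C2, rep(0, length(scales)), tolerance = 1e-12)
  expect_equal(cc$C3, rep(0, length(scales)), tolerance = 1e-12)
  fit <- fit_cumulant_slopes(cc, range(scales))
  expect_equal(fit$c1, alpha, tolerance = 1e-10)
  expect_equal(fit$c2_raw, 0, tolerance = 1e-10)
})

test_that("injected Gaussian magnitudes have vanishing third cumulant", {
  set.seed(31)
  scales <- 2^seq(4, 7, by = 0.25)
  n_lines <- 400
  mags <- exp(matrix(rnorm(n_lines * length(scales), mean = 1, sd = 0.5),
                     nrow = n_lines))
  cc <- compute_magnitude_cumulants(make_skeleton(mags, scales))
  # k3 of a Gaussian is 0; se(k3) ~ sqrt(6/n) sigma^3
  se3 <- sqrt(6 / n_lines) * 0.5^3
  expect_true(all(abs(cc$C3) < 4 * se3 + 0.01))
})

test_that("single impulse-response line gives C1(a) = ln kappa - ln a", {
  # one maxima line with the delta ridge modulus kappa / a
  scales <- 2^seq(4, 9, by = 0.25)
  kappa <- abs(eval_wavelet(2, 0))
  sk <- make_skeleton(matrix(kappa / scales, nrow = 1), scales)
  cc <- suppressWarnings(compute_magnitude_cumulants(sk, min_lines = 1L))
  fit <- lm(cc$C1 ~ log(cc$scales))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), log(kappa), tolerance = 1e-10)
  # and the same law measured on a real delta skeleton's central ridge
  n <- 2^14
  real <- build_skeleton(cwt_transform(
    gen_fixture(fixture_spec("delta", n = n, location = n / 2)),
    scale_grid(2^4, 2^9, 8), order = 2))
  l <- real$lines[[central_line(real, n / 2)]]
  a <- real$scales[l$birth:l$death]
  fit2 <- lm(log(l$modulus) ~ log(a))
  expect_equal(unname(coef(fit2)[2]), -1, tolerance = 0.02)
  expect_equal(unname(coef(fit2)[1]), log(kappa), tolerance = 0.05)
})

test_that("C1(a) equals the canonical h(q = 0, a) exactly", {
  wn <- gen_fixture(fixture_spec("white_noise", n = 2^12, seed = 23))
  sk <- build_skeleton(cwt_transform(wn, scale_grid(2^4, 2^7, 8), order = 2))
  ens <- partition_functions(sk, q = c(0, 1))
  cc <- compute_magnitude_cumulants(sk, scale_index = ens$scale_index)
  expect_equal(cc$C1, ens$h_canon[1, ], tolerance = 1e-12)
})

test_that("cumulant slope fits recover crafted exact scalings", {
  scales <- 2^seq(4, 8, by = 0.25)
  la <- log(scales)
  set.seed(7)
  n_lines <- 200
  # construct magnitudes whose sample C1/C2 follow exact lines by applying
  # an affine map to fixed draws at every scale
  z <- rnorm(n_lines)
  z <- (z - mean(z)) / sd(z)
  c1t <- -0.4; c2t <- 0.06; C2_0 <- 1.2
  mags <- sapply(seq_along(scales), function(s)
    exp(c1t * la[s] + sqrt(C2_0 - c2t * la[s]) * z))
  cc <- compute_magnitude_cumulants(make_skeleton(mags, scales))
  fit <- fit_cumulant_slopes(cc, range(scales))
  expect_equal(fit$c1, c1t, tolerance = 1e-10)
  expect_equal(fit$c2, c2t, tolerance = 1e-10)
  # c0 estimate from crafted N_a ~ a^(-0.9): fabricate counts via skeleton
  cc2 <- cc
  cc2$N_a <- as.integer(round(4000 * scales^(-0.9)))
  fit2 <- fit_cumulant_slopes(cc2, range(scales))
  expect_equal(fit2$c0, 0.9, tolerance = 0.01)
  expect_error(fit_cumulant_slopes(cc, c(16, 18)), "fewer than 4")
})

test_that("tau assembled from coefficients matches the quadratic formula", {
  qs <- structure(list(c0 = 1.01, c1 = -0.34, c2 = 0.053, c3 = 0,
                       method = "cumulants"), class = "quadratic_spectrum")
  q <- seq(-1, 5, 0.5)
  expect_equal(tau_from_coefficients(qs, q),
               -1.01 - 0.34 * q - 0.053 * q^2 / 2, tolerance = 1e-12)
})
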