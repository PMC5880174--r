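# Independent oracles and fixture builders used across test files.

# Exact fractional-Gaussian-noise autocovariance, written out from the
# definition (independent of the generator's internal helper).
oracle_fgn_acf <- function(H, lags) {
  0.5 * (abs(lags + 1)^(2 * H) - 2 * abs(lags)^(2 * H) + abs(lags - 1)^(2 * H))
}

# Spectral density of fGn from its covariance (finite cosine sum); used to
# compute the effective log-log slope over a band, the honest reference for
# the Welch estimate.
oracle_fgn_psd <- function(H, freq, n_lags = 4096L) {
  g <- oracle_fgn_acf(H, 0:n_lags)
  vapply(freq, function(f) g[1] + 2 * sum(g[-1] * cos(2 * pi * f * (1:n_lags))),
         numeric(1))
}

oracle_fgn_band_slope <- function(H, band, n_lags = 4096L) {
  f <- exp(seq(log(band[1]), log(band[2]), length.out = 64))
  s <- oracle_fgn_psd(H, f, n_lags)
  unname(stats::coef(stats::lm(log(s) ~ log(f)))[2])
}

# Closed-form CWT of a Gaussian bump exp(-t^2 / (2 sigma^2)) analyzed with
# the second Gaussian derivative at L1 normalization: analytic convolution
# of two Gaussians, differentiated twice.
oracle_bump_cwt_g2 <- function(b, a, sigma) {
  s2 <- sigma^2 + a^2
  sqrt(2 * pi) * sigma * a^2 / sqrt(s2) * ((b^2 - s2) / s2^2) * exp(-b^2 / (2 * s2))
}

# Build a synthetic skeleton whose line magnitudes are chosen directly, to
# test the statistics modules in isolation from the transform. `mags` is an
# n_lines x n_scales matrix; every line spans all scales, at distinct times.
make_skeleton <- function(mags, scales, times = NULL, dt = 1) {
  n_lines <- nrow(mags); S <- ncol(mags)
  stopifnot(length(scales) == S)
  if (is.null(times))
    times <- matrix(rep(seq(10, by = 50, length.out = n_lines), S), ncol = S)
  lines <- lapply(seq_len(n_lines), function(i) {
    list(birth = 1L, death = S, time = as.integer(times[i, ]),
         modulus = as.numeric(mags[i, ]), value = as.numeric(mags[i, ]))
  })
  alive <- lapply(seq_len(S), function(s) seq_len(n_lines))
  structure(list(lines = lines, scales = scales, voices = NA_real_,
                 order = 2L, dt = dt, n_times = max(times) + 100L,
                 alive = alive),
            class = "wtmm_skeleton")
}

# Longest maxima line in a skeleton whose finest-scale position is nearest
# to `loc` (used to pick the central line of an isolated singularity).
central_line <- function(skeleton, loc) {
  span <- vapply(skeleton$lines, function(l) l$death - l$birth, numeric(1))
  cand <- which(span >= max(span) * 0.9)
  pos <- vapply(skeleton$lines[cand], function(l) l$time[1], numeric(1))
  cand[which.min(abs(pos - loc))]
}
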