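#' Specification of a fractional Brownian motion / Gaussian noise signal
#'
#' Monofractal reference signal: every point has the same Hölder exponent H,
#' so the multifractal spectrum degenerates to a single point (h, D) = (H, 1)
#' and the intermittency coefficient c2 is exactly zero.
#'
#' @param H Hurst exponent, strictly between 0 and 1.
#' @param n number of samples; a power of two, at least 2^8.
#' @param seed integer RNG seed; the generator is a pure function of the spec.
#' @param output `"path"` for fractional Brownian motion, `"increments"` for
#'   the stationary fractional Gaussian noise.
#' @param dt sampling interval in seconds (defaults to 1, i.e. sample units).
#' @return an object of class `fbm_spec`.
#' @export
fbm_spec <- function(H, n, seed = 1L, output = c("path", "increments"), dt = 1) {
  output <- match.arg(output)
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1)
    stop("invalid-parameter: H must lie strictly inside (0, 1)", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L^8L || bitwAnd(n, n - 1L) != 0L)
    stop("invalid-parameter: n must be a power of two with n >= 256", call. = FALSE)
  structure(list(H = H, n = n, seed = as.integer(seed), output = output, dt = dt),
            class = "fbm_spec")
}

# Exact fGn autocovariance at lags 0..(n-1), unit variance.
fgn_covariance <- function(H, n) {
  k <- 0:(n - 1)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Generate fractional Brownian motion with exact covariance
#'
#' Circulant embedding (Dietrich--Newsam) of the exact fractional Gaussian
#' noise covariance: the returned increments have, in expectation, exactly the
#' fGn autocovariance, enabling closed-form tests of every downstream
#' estimator. Fails loudly if the embedding is not nonnegative definite.
#'
#' @param spec an [fbm_spec()].
#' @return a [signal_trace()] of length `spec$n`; the embedded covariance is
#'   attached as attribute `"acf"`.
#' @examples
#' tr <- gen_fbm(fbm_spec(H = 0.5, n = 1024, seed = 2, output = "increments"))
#' var(tr$values)  # close to 1
#' @export
gen_fbm <- function(spec) {
  stopifnot(inherits(spec, "fbm_spec"))
  n <- spec$n
  g <- fgn_covariance(spec$H, n + 1L)          # lags 0..n
  row <- c(g, rev(g[2:n]))                     # circulant first row, length 2n
  m <- length(row)
  lam <- Re(stats::fft(row))
  if (min(lam) < -1e-8 * max(lam))
    stop("invalid-parameter: circulant embedding not nonnegative definite", call. = FALSE)
  lam <- pmax(lam, 0)
  inc <- with_seed(spec$seed, {
    w <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    y <- stats::fft(sqrt(lam) * w) / sqrt(m)
    Re(y)[seq_len(n)]
  })
  vals <- if (spec$output == "path") cumsum(inc) else inc
  out <- signal_trace(vals, dt = spec$dt,
                      label = sprintf("fbm_H%.3g_%s", spec$H, spec$output))
  attr(out, "acf") <- g
  out
}

## ---- log-normal wavelet cascades --------------------------------------------

# Compactly supported polynomial synthesis wavelet: the order-th derivative
# of the bump (u(1-u))^(order+2) on [0, 1], sampled at npts points and
# normalized to unit maximum modulus. Has exactly `order` vanishing moments
# (integration by parts; all boundary terms vanish) and support of exactly
# one cell, so same-level atoms never overlap -- the property that lets a
# single realization carry clean one-point magnitude statistics.
synthesis_wavelet <- function(order, npts) {
  order <- as.integer(order)
  if (order < 1L)
    stop("invalid-parameter: synthesis wavelet order must be >= 1", call. = FALSE)
  p <- order + 2L
  co <- numeric(2L * p + 1L)                   # coefficients of u^0..u^(2p)
  for (k in 0:p) co[p + k + 1L] <- (-1)^k * choose(p, k)
  for (d in seq_len(order)) {                  # differentiate `order` times
    nco <- numeric(length(co) - 1L)
    for (pw in seq_along(nco)) nco[pw] <- co[pw + 1L] * pw
    co <- nco
  }
  u <- (seq_len(npts) - 0.5) / npts
  v <- vapply(u, function(x) sum(co * x^(seq_along(co) - 1)), numeric(1))
  v / max(abs(v))
}

#' Specification of a log-normal wavelet-cascade signal
#'
#' Synthetic multifractal noise built on a dyadic wavelet tree: the wavelet
#' coefficient at depth j, position k has magnitude exp(omega_jk) where omega
#' is Gaussian with mean and variance linear in depth. In `"multiplicative"`
#' mode omega is the running sum of i.i.d. Gaussian innovations down the
#' ancestry path (a genuine cascade: magnitudes are correlated across scale
#' and time); in `"uncorrelated"` mode each cell draws omega independently
#' with the same depth-wise marginal law (identical one-point statistics, no
#' cascade structure -- "multifractal white noise"). Both modes share the
#' theoretical spectrum tau(q) = -1 + c1*q - c2*q^2/2.
#'
#' @param c1_target mean-magnitude slope c1 (negative for singular noise).
#' @param c2_target intermittency coefficient c2 >= 0.
#' @param n_octaves number of dyadic levels J; signal length is 2^J; J >= 8.
#' @param mode `"multiplicative"` or `"uncorrelated"`.
#' @param synthesis_wavelet_order vanishing moments of the compactly
#'   supported polynomial synthesis wavelet (default 3); each atom spans
#'   exactly one dyadic cell, so same-level atoms never overlap. Analysis
#'   wavelets need not match the synthesis family.
#' @param seed integer RNG seed.
#' @return an object of class `cascade_spec`.
#' @export
cascade_spec <- function(c1_target, c2_target, n_octaves,
                         mode = c("multiplicative", "uncorrelated"),
                         synthesis_wavelet_order = 3L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(c2_target) || c2_target < 0)
    stop("invalid-parameter: c2_target must be >= 0", call. = FALSE)
  n_octaves <- as.integer(n_octaves)
  if (n_octaves < 8L)
    stop("invalid-parameter: n_octaves >= 8 needed for three decades of scaling",
         call. = FALSE)
  if (as.integer(synthesis_wavelet_order) < 1L)
    stop("invalid-parameter: synthesis_wavelet_order must be >= 1", call. = FALSE)
  structure(list(c1_target = c1_target, c2_target = c2_target,
                 n_octaves = n_octaves, mode = mode,
                 synthesis_wavelet_order = as.integer(synthesis_wavelet_order),
                 seed = as.integer(seed)),
            class = "cascade_spec")
}

#' Generate a log-normal wavelet-cascade signal
#'
#' Inverse dyadic wavelet summation: for depth j = 1..J the 2^j coefficients
#' s_jk * exp(omega_jk) are placed on the dyadic grid and each multiplies a
#' copy of the compactly supported synthesis wavelet spanning exactly its
#' cell (2^(J-j) samples); levels are summed. Signs s_jk are independent
#' +/-1 -- all scaling information is carried by the magnitudes. Per level
#' the innovation law is N(-c1*ln 2, c2*ln 2), the parametrization (with
#' scale measured in samples) under which one-point statistics give
#' tau(q) = -1 + c1*q - c2*q^2/2. Levels whose cells are narrower than
#' `min_cell` samples are omitted: they sit far below any analyzable scale
#' and their crudely sampled atoms would only inject broadband artifacts.
#'
#' @param spec a [cascade_spec()].
#' @param min_cell smallest synthesized cell width in samples (default 8).
#' @return a [signal_trace()] of length 2^`n_octaves`; the full magnitude tree
#'   is attached as attribute `"omega"` (list of per-depth vectors) for
#'   verification, and the per-level law as attributes `"level_mean"`,
#'   `"level_var"`.
#' @export
gen_cascade_signal <- function(spec, min_cell = 8L) {
  stopifnot(inherits(spec, "cascade_spec"))
  J <- spec$n_octaves
  n <- 2L^J
  m_lvl <- -spec$c1_target * log(2)
  s_lvl <- sqrt(spec$c2_target * log(2))

  omega <- vector("list", J)
  signs <- vector("list", J)
  with_seed(spec$seed, {
    if (spec$mode == "multiplicative") {
      parent <- 0
      for (j in seq_len(J)) {
        xi <- stats::rnorm(2L^j, mean = m_lvl, sd = s_lvl)
        omega[[j]] <- rep(parent, each = 2L) + xi
        parent <- omega[[j]]
      }
    } else {
      for (j in seq_len(J))
        omega[[j]] <- stats::rnorm(2L^j, mean = j * m_lvl, sd = sqrt(j) * s_lvl)
    }
    for (j in seq_len(J))
      signs[[j]] <- sample(c(-1, 1), 2L^j, replace = TRUE)
  })

  x <- numeric(n)
  for (j in seq_len(J)) {
    w <- 2L^(J - j)
    if (w < min_cell) next
    atom <- synthesis_wavelet(spec$synthesis_wavelet_order, w)
    d <- numeric(n)
    d[1L + (0:(2L^j - 1L)) * w] <- signs[[j]] * exp(omega[[j]])
    x <- x + Re(stats::fft(stats::fft(d) * stats::fft(c(atom, numeric(n - w))),
                           inverse = TRUE)) / n
  }
  out <- signal_trace(x, dt = 1,
                      label = sprintf("cascade_%s_c1%.3g_c2%.3g", spec$mode,
                                      spec$c1_target, spec$c2_target))
  attr(out, "omega") <- omega
  attr(out, "level_mean") <- m_lvl
  attr(out, "level_var") <- s_lvl^2
  out
}

## ---- deterministic fixtures -------------------------------------------------

#' Specification of a deterministic test fixture
#'
#' Elementary signals whose wavelet behaviour is known in closed form: a unit
#' impulse (Hölder exponent h = -1 along its maxima line), a step (h = 0), a
#' ramp, an exactly periodic sine, and seeded white noise.
#'
#' @param kind one of `"delta"`, `"step"`, `"ramp"`, `"sine"`, `"white_noise"`.
#' @param n number of samples.
#' @param location 0-based sample index of the delta / step onset.
#' @param amplitude signal amplitude (slope per second for `"ramp"`).
#' @param period period in samples for `"sine"`.
#' @param seed RNG seed for `"white_noise"`.
#' @param dt sampling interval in seconds.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("delta", "step", "ramp", "sine", "white_noise"),
                         n, location = NULL, amplitude = 1, period = NULL,
                         seed = 1L, dt = 1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("invalid-parameter: unknown fixture kind",
                                            call. = FALSE))
  n <- as.integer(n)
  if (n < 2L) stop("invalid-parameter: n must be >= 2", call. = FALSE)
  if (kind %in% c("delta", "step")) {
    if (is.null(location)) location <- n %/% 2L
    location <- as.integer(location)
    if (location < 0L || location >= n)
      stop("invalid-parameter: location must satisfy 0 <= location < n", call. = FALSE)
  }
  if (kind == "sine") {
    if (is.null(period))
      stop("invalid-parameter: sine fixture needs a period", call. = FALSE)
    period <- as.integer(period)
    if (period < 2L) stop("invalid-parameter: period must be >= 2 samples", call. = FALSE)
  }
  structure(list(kind = kind, n = n, location = location, amplitude = amplitude,
                 period = period, seed = as.integer(seed), dt = dt),
            class = "fixture_spec")
}

#' Generate a deterministic (or seeded) fixture signal
#' @param spec a [fixture_spec()].
#' @return a [signal_trace()].
#' @export
gen_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n
  i <- 0:(n - 1L)
  vals <- switch(spec$kind,
    delta = { v <- numeric(n); v[spec$location + 1L] <- spec$amplitude; v },
    step  = ifelse(i >= spec$location, spec$amplitude, 0),
    ramp  = spec$amplitude * i * spec$dt,
    sine  = spec$amplitude * sin(2 * pi * (i %% spec$period) / spec$period),
    white_noise = with_seed(spec$seed, stats::rnorm(n)))
  signal_trace(vals, dt = spec$dt, label = paste0("fixture_", spec$kind))
}

## ---- surrogate electrograms -------------------------------------------------

#' Specification of a surrogate atrial-fibrillation electrogram
#'
#' Emulates a bipolar intracardiac recording during AF: biphasic deflections
#' (each the derivative of a Gaussian, duration `deflection_width`) at
#' stochastic interbeat intervals with mean rate 3-10 Hz, optional log-normal
#' multifractal modulation of the log-amplitudes, and additive baseline noise.
#' This is a statistical surrogate, not a tissue model.
#'
#' @param duration recording length in seconds.
#' @param dt sampling interval in seconds.
#' @param mean_rate mean activation rate in Hz (AF range is roughly 3-10 Hz).
#' @param rate_cv coefficient of variation of the interbeat intervals.
#' @param deflection_width duration of one deflection in seconds; must be
#'   shorter than the mean interbeat interval.
#' @param amplitude_magnitude optional [cascade_spec()] whose signal modulates
#'   the per-beat log-amplitudes.
#' @param baseline_noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return an object of class `egm_spec`.
#' @export
egm_spec <- function(duration, dt = 1e-3, mean_rate = 5, rate_cv = 0.2,
                     deflection_width = 0.02, amplitude_magnitude = NULL,
                     baseline_noise_sd = 0, seed = 1L) {
  if (dt <= 0) stop("invalid-parameter: dt must be > 0", call. = FALSE)
  if (mean_rate * duration < 10)
    stop("invalid-parameter: need mean_rate * duration >= 10 beats", call. = FALSE)
  if (deflection_width >= 1 / mean_rate)
    stop("invalid-parameter: deflection_width must be below the mean interbeat interval",
         call. = FALSE)
  if (!is.null(amplitude_magnitude) && !inherits(amplitude_magnitude, "cascade_spec"))
    stop("invalid-parameter: amplitude_magnitude must be a cascade_spec or NULL",
         call. = FALSE)
  structure(list(duration = duration, dt = dt, mean_rate = mean_rate,
                 rate_cv = rate_cv, deflection_width = deflection_width,
                 amplitude_magnitude = amplitude_magnitude,
                 baseline_noise_sd = baseline_noise_sd, seed = as.integer(seed)),
            class = "egm_spec")
}

# Biphasic deflection template: derivative of a Gaussian spanning `width`
# seconds (+-3 sigma), unit peak amplitude.
egm_template <- function(width, dt) {
  sigma <- width / 6
  tt <- seq(-3 * sigma, 3 * sigma, by = dt)
  w <- -tt / sigma^2 * exp(-tt^2 / (2 * sigma^2))
  w / max(abs(w))
}

#' Generate a surrogate atrial-fibrillation electrogram
#'
#' @param spec an [egm_spec()].
#' @return a [signal_trace()] (units mV, nominal); beat times in seconds are
#'   attached as attribute `"beat_times"`, per-beat amplitudes as `"beat_amp"`.
#' @export
gen_surrogate_egm <- function(spec) {
  stopifnot(inherits(spec, "egm_spec"))
  n <- as.integer(round(spec$duration / spec$dt))
  mu <- 1 / spec$mean_rate
  with_seed(spec$seed, {
    n_max <- as.integer(ceiling(spec$duration / mu * 3)) + 10L
    gaps <- if (spec$rate_cv > 0) {
      shape <- 1 / spec$rate_cv^2
      stats::rgamma(n_max, shape = shape, scale = mu / shape)
    } else rep(mu, n_max)
    beats <- cumsum(gaps)
    beats <- beats[beats < spec$duration - spec$deflection_width]
    amp <- rep(1, length(beats))
    if (!is.null(spec$amplitude_magnitude)) {
      mod <- gen_cascade_signal(spec$amplitude_magnitude)
      z <- mod$values[1L + ((seq_along(beats) - 1L) %% length(mod$values))]
      z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
      amp <- exp(0.5 * z)
    }
    tmpl <- egm_template(spec$deflection_width, spec$dt)
    half <- (length(tmpl) - 1L) %/% 2L
    x <- numeric(n)
    for (b in seq_along(beats)) {
      ctr <- as.integer(round(beats[b] / spec$dt)) + 1L
      lo <- ctr - half; hi <- ctr + (length(tmpl) - 1L - half)
      sel <- lo:hi
      ok <- sel >= 1L & sel <= n
      x[sel[ok]] <- x[sel[ok]] + amp[b] * tmpl[ok]
    }
    if (spec$baseline_noise_sd > 0)
      x <- x + stats::rnorm(n, sd = spec$baseline_noise_sd)
    out <- signal_trace(x, dt = spec$dt, label = "surrogate_egm", units = "mV")
    attr(out, "beat_times") <- beats
    attr(out, "beat_amp") <- amp
    out
  })
}

#' Theoretical multifractal exponents tau(q) of a synthetic spec
#'
#' Closed-form tau(q): `q*H - 1` for a fractional Brownian path,
#' `-1 + c1*q - c2*q^2/2` for the log-normal cascades (both modes share it).
#'
#' @param spec an [fbm_spec()] or [cascade_spec()].
#' @param q numeric grid of moment orders.
#' @return numeric vector of tau(q) values.
#' @examples
#' closed_form_tau(cascade_spec(-0.34, 0.053, 10), q = c(0, 2))
#' @export
closed_form_tau <- function(spec, q) {
  if (!all(is.finite(q))) stop("invalid-parameter: q grid must be finite", call. = FALSE)
  if (inherits(spec, "fbm_spec")) {
    q * spec$H - 1
  } else if (inherits(spec, "cascade_spec")) {
    -1 + spec$c1_target * q - spec$c2_target * q^2 / 2
  } else {
    stop("invalid-parameter: spec must be an fbm_spec or cascade_spec", call. = FALSE)
  }
}
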