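#' Gaussian-derivative analyzing wavelet
#'
#' Evaluates g^(N)(t) = d^N/dt^N exp(-t^2/2), the standard analyzing wavelets
#' of the WTMM method. g^(N) has exactly N vanishing moments, so the wavelet
#' transform is blind to polynomial trends of degree below N. Closed form via
#' Hermite polynomials: g^(N)(t) = (-1)^N He_N(t) exp(-t^2/2).
#'
#' @param order number of vanishing moments N >= 1 (1-3 are the orders used
#'   in practice; any positive integer is accepted).
#' @param grid numeric vector of evaluation points (wavelet units).
#' @return numeric vector of wavelet values on `grid`.
#' @examples
#' eval_wavelet(2, 0)   # (t^2 - 1) exp(-t^2/2) at t = 0 is -1
#' @export
eval_wavelet <- function(order, grid) {
  order <- as.integer(order)
  if (order < 1L)
    stop("invalid-parameter: wavelet order must be >= 1", call. = FALSE)
  # probabilists' Hermite polynomials by recurrence: He_{k+1} = t He_k - k He_{k-1}
  he_prev <- rep(1, length(grid))
  he <- grid
  if (order >= 2L) {
    for (k in 1:(order - 1L)) {
      he_next <- grid * he - k * he_prev
      he_prev <- he
      he <- he_next
    }
  }
  (-1)^order * he * exp(-grid^2 / 2)
}

#' Dyadic scale grid
#'
#' Log2-spaced scales with `voices` points per octave, the grid on which all
#' scaling fits are performed.
#'
#' @param a_min,a_max smallest / largest scale in samples.
#' @param voices voices per octave (default 8).
#' @return numeric vector of strictly increasing scales (samples).
#' @export
scale_grid <- function(a_min, a_max, voices = 8L) {
  if (a_min <= 0 || a_max <= a_min)
    stop("invalid-parameter: need 0 < a_min < a_max", call. = FALSE)
  n_oct <- log2(a_max / a_min)
  2^(log2(a_min) + (0:floor(n_oct * voices + 1e-9)) / voices)
}

#' Continuous wavelet transform on a time-scale grid
#'
#' Computes T(t, a) = (1/a) sum_t' x(t') g^(N)((t' - t)/a) over all requested
#' scales (L1 normalization, so that |T| ~ a^h along maxima lines with h the
#' Hölder exponent). Convolution is FFT-based with reflection padding; the
#' validity mask excludes one numerical support radius (5a samples, where the
#' Gaussian envelope is below ~4e-6) at each boundary -- the cone of
#' influence.
#'
#' @param trace a [signal_trace()].
#' @param scales numeric vector of scales in samples, strictly increasing
#'   (e.g. from [scale_grid()]). Scales too large for the signal span are
#'   dropped with a warning.
#' @param order analyzing-wavelet order N (vanishing moments), default 3.
#' @param support_radius numerical support of the wavelet in units of a,
#'   default 5.
#' @param voices voices per octave of `scales` if known (stored for stderr
#'   inflation downstream); inferred from the grid when `NULL`.
#' @return an object of class `wavelet_plane`: list with `coefficients`
#'   (time x scale matrix), `scales`, `times` (sample indices), `order`,
#'   `norm = "L1"`, `valid_mask` (same shape as `coefficients`), `dt`,
#'   `voices`.
#' @export
cwt_transform <- function(trace, scales, order = 3L, support_radius = 5,
                          voices = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values
  n <- length(x)
  scales <- sort(as.numeric(scales))
  if (any(diff(scales) <= 0))
    stop("invalid-parameter: scales must be strictly increasing", call. = FALSE)
  keep <- scales * support_radius * 2 < n
  if (!all(keep)) {
    warning(sprintf("dropping %d scale(s) exceeding the signal span", sum(!keep)))
    scales <- scales[keep]
  }
  if (length(scales) == 0L)
    stop("invalid-input: no scale fits inside the signal span", call. = FALSE)
  if (is.null(voices)) {
    lr <- diff(log2(scales))
    voices <- if (length(lr) >= 2L && isTRUE(stats::sd(lr) < 1e-8 * mean(lr)))
      round(1 / lr[1])
    else if (length(lr) == 1L && lr[1] > 0) round(1 / lr[1])
    else NA_real_
  }

  pad <- as.integer(ceiling(support_radius * max(scales)))
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  nfft <- stats::nextn(np + 2L * pad + 1L, 2L)
  fx <- stats::fft(c(xp, numeric(nfft - np)))

  coef <- matrix(NA_real_, nrow = n, ncol = length(scales))
  mask <- matrix(FALSE, nrow = n, ncol = length(scales))
  for (s in seq_along(scales)) {
    a <- scales[s]
    L <- as.integer(ceiling(support_radius * a))
    k <- (-L):L
    w <- eval_wavelet(order, k / a) / a
    # cross-correlation: T(t) = sum_k x(t + k) w(k); as circular convolution
    # place reversed kernel so that lag 0 lands on index 1
    kern <- numeric(nfft)
    kern[1L] <- w[L + 1L]
    kern[2:(L + 1L)] <- w[(L + 2L):(2L * L + 1L)]           # positive lags
    kern[(nfft - L + 1L):nfft] <- w[1:L]                    # negative lags
    # conj trick: correlation x*w = ifft(fft(x) * Conj(fft(w_zero_phase)))
    Tfull <- Re(stats::fft(fx * Conj(stats::fft(kern)), inverse = TRUE)) / nfft
    coef[, s] <- Tfull[(pad + 1L):(pad + n)]
    lo <- ceiling(support_radius * a)
    valid <- seq_len(n) > lo & seq_len(n) <= n - lo
    mask[valid, s] <- TRUE
  }
  structure(list(coefficients = coef, scales = scales, times = seq_len(n),
                 order = order, norm = "L1", valid_mask = mask,
                 dt = trace$dt, voices = voices,
                 support_radius = support_radius, label = trace$label),
            class = "wavelet_plane")
}

#' @export
print.wavelet_plane <- function(x, ...) {
  cat(sprintf("<wavelet_plane> g^(%d), %d times x %d scales (a = %.3g..%.3g samples), L1 norm\n",
              x$order, nrow(x$coefficients), length(x$scales),
              min(x$scales), max(x$scales)))
  invisible(x)
}
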