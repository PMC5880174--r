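#' Cumulants of the magnitude ln|T| across scales
#'
#' For each scale a, computes the first three sample cumulants of the
#' magnitudes ln|T| over the line set L(a): C1 the mean, C2 the (unbiased)
#' variance, C3 the third k-statistic. Under log-normal multifractal scaling
#' C1(a) ~ c1 ln a, C2(a) ~ -c2 ln a and C3(a) ~ c3 ln a, so the spectrum
#' coefficients follow from just three linear regressions. Lines carry
#' uniform weight (one magnitude per line, the same sets the moment method
#' sums over).
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param scale_index scale positions to use (default all); scales with
#'   fewer than `min_lines` lines are dropped with a warning.
#' @param value_mode passed to [line_set_at_scale()].
#' @param min_lines minimum |L(a)| per scale (default 10).
#' @return an object of class `cumulant_curves`: `scales`, `C1`, `C2`, `C3`,
#'   `N_a`, `voices`, `value_mode`.
#' @export
compute_magnitude_cumulants <- function(skeleton, scale_index = NULL,
                                        value_mode = c("value", "sup"),
                                        min_lines = 10L) {
  stopifnot(inherits(skeleton, "wtmm_skeleton"))
  value_mode <- match.arg(value_mode)
  if (is.null(scale_index)) scale_index <- seq_along(skeleton$scales)
  sets <- lapply(scale_index, function(s)
    line_set_at_scale(skeleton, s, value_mode = value_mode))
  nmag <- vapply(sets, nrow, integer(1))
  if (any(nmag < min_lines)) {
    warning(sprintf("dropping %d scale(s) with |L(a)| < %d",
                    sum(nmag < min_lines), min_lines))
    keep <- nmag >= min_lines
    scale_index <- scale_index[keep]; sets <- sets[keep]; nmag <- nmag[keep]
  }
  if (!length(scale_index))
    stop("invalid-input: no scale has enough maxima lines", call. = FALSE)
  C1 <- C2 <- C3 <- numeric(length(scale_index))
  for (k in seq_along(sets)) {
    m <- log(sets[[k]]$mag)
    n <- length(m)
    mu <- mean(m)
    C1[k] <- mu
    C2[k] <- sum((m - mu)^2) / (n - 1)
    C3[k] <- n^2 / ((n - 1) * (n - 2)) * mean((m - mu)^3)
  }
  structure(list(scales = skeleton$scales[scale_index], C1 = C1, C2 = C2,
                 C3 = C3, N_a = nmag, voices = skeleton$voices,
                 value_mode = value_mode),
            class = "cumulant_curves")
}

#' @export
print.cumulant_curves <- function(x, ...) {
  cat(sprintf("<cumulant_curves> %d scales (a = %.3g..%.3g), N_a = %d..%d\n",
              length(x$scales), min(x$scales), max(x$scales),
              min(x$N_a), max(x$N_a)))
  invisible(x)
}

#' Spectrum coefficients from magnitude-cumulant slopes
#'
#' Linear regressions over ln a in the fit range give c1* (slope of C1),
#' c2* (minus the slope of C2), c3* (slope of C3) and c0 (minus the slope of
#' ln N_a, the fractal dimension of the singularity support: N_a ~ a^(-Df)).
#' Standard errors are regression stderr inflated by sqrt(voices) for the
#' dependence between voices of the same octave. c2 is constrained
#' nonnegative; the raw value is kept in `c2_raw`.
#'
#' @param curves a `cumulant_curves`.
#' @param fit_range length-2 numeric scale range (samples) with >= 4 scales.
#' @return an object of class `quadratic_spectrum` with
#'   `method = "cumulants"`.
#' @export
fit_cumulant_slopes <- function(curves, fit_range) {
  stopifnot(inherits(curves, "cumulant_curves"))
  a <- curves$scales
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    stop("invalid-parameter: fit_range must be (a_min, a_max)", call. = FALSE)
  sel <- a >= fit_range[1] & a <= fit_range[2]
  if (sum(sel) < 4L)
    stop("invalid-parameter: fewer than 4 scale points in fit_range", call. = FALSE)
  la <- log(a[sel])
  infl <- sqrt(max(1, if (is.na(curves$voices)) 1 else curves$voices))
  sl <- function(y) {
    f <- stats::lm.fit(cbind(1, la), y)
    sxx <- sum((la - mean(la))^2)
    se <- sqrt(sum(f$residuals^2) / max(length(y) - 2L, 1L) / sxx)
    c(unname(f$coefficients[2L]), se * infl)
  }
  f1 <- sl(curves$C1[sel]); f2 <- sl(curves$C2[sel]); f3 <- sl(curves$C3[sel])
  f0 <- sl(log(curves$N_a[sel]))
  c2_raw <- -f2[1]
  structure(list(c0 = -f0[1], c0_se = f0[2],
                 c1 = f1[1], c1_se = f1[2],
                 c2 = max(0, c2_raw), c2_raw = c2_raw, c2_se = f2[2],
                 c3 = f3[1], c3_se = f3[2],
                 fit_range = fit_range, method = "cumulants"),
            class = "quadratic_spectrum")
}

#' tau(q) implied by cumulant (or quadratic) coefficients
#'
#' Assembles tau(q) = -c0 + c1 q - c2 q^2/2 + c3 q^3/6 from an estimated
#' coefficient set, for comparison with the moment-method tau(q).
#'
#' @param spec a `quadratic_spectrum` (from [fit_quadratic_tau()] or
#'   [fit_cumulant_slopes()]).
#' @param q moment-order grid.
#' @return numeric vector tau(q).
#' @export
tau_from_coefficients <- function(spec, q) {
  stopifnot(inherits(spec, "quadratic_spectrum"))
  c3 <- if (is.null(spec$c3) || !is.finite(spec$c3)) 0 else spec$c3
  -spec$c0 + spec$c1 * q - spec$c2 * q^2 / 2 + c3 * q^3 / 6
}

#' Cumulant curves as TSV
#' @param curves a `cumulant_curves`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
cumulants_to_tsv <- function(curves, path) {
  df <- data.frame(scale = curves$scales, C1 = curves$C1, C2 = curves$C2,
                   C3 = curves$C3, N_a = curves$N_a)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
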