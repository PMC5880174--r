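logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Partition functions and canonical expectation values
#'
#' For each requested scale a, computes over the line set L(a):
#' Z(q, a) = sum_l |T|^q, the canonical mean Hölder estimate
#' h(q, a) = sum_l ln|T| W(q, l, a) and entropy D(q, a) = sum_l W ln W, where
#' W = |T|^q / Z is the Boltzmann weight of line l. All sums are evaluated in
#' log space so large negative q do not underflow. Natural logarithms
#' throughout.
#'
#' @param skeleton a `wtmm_skeleton` from [build_skeleton()].
#' @param q numeric grid of moment orders (default -1..5 step 0.25, the range
#'   over which value-mode WTMM statistics are stable).
#' @param scale_index integer vector of scale positions to use (default: all
#'   scales with a nonempty L(a); empty scales are dropped with a warning).
#' @param value_mode passed to [line_set_at_scale()].
#' @return an object of class `partition_ensemble`: `q`, `scales`,
#'   `scale_index`, `lnZ` (q x scale matrix), `h_canon`, `D_canon`, `N_a`,
#'   `value_mode`, `voices`, plus the per-scale magnitude sets in `mags`.
#' @export
partition_functions <- function(skeleton, q = seq(-1, 5, by = 0.25),
                                scale_index = NULL,
                                value_mode = c("value", "sup")) {
  stopifnot(inherits(skeleton, "wtmm_skeleton"))
  value_mode <- match.arg(value_mode)
  if (!all(is.finite(q)))
    stop("invalid-parameter: q grid must be finite", call. = FALSE)
  if (is.null(scale_index)) scale_index <- seq_along(skeleton$scales)
  sets <- lapply(scale_index, function(s)
    line_set_at_scale(skeleton, s, value_mode = value_mode))
  nmag <- vapply(sets, nrow, integer(1))
  if (any(nmag == 0L)) {
    warning(sprintf("dropping %d scale(s) with empty L(a)", sum(nmag == 0L)))
    keep <- nmag > 0L
    scale_index <- scale_index[keep]; sets <- sets[keep]; nmag <- nmag[keep]
  }
  if (!length(scale_index))
    stop("invalid-input: no scale has a nonempty line set", call. = FALSE)
  nq <- length(q); ns <- length(scale_index)
  lnZ <- matrix(NA_real_, nq, ns)
  hC <- matrix(NA_real_, nq, ns)
  dC <- matrix(NA_real_, nq, ns)
  for (s in seq_len(ns)) {
    lnv <- log(sets[[s]]$mag)
    for (k in seq_len(nq)) {
      lz <- logsumexp(q[k] * lnv)
      lnW <- q[k] * lnv - lz
      W <- exp(lnW)
      lnZ[k, s] <- lz
      hC[k, s] <- sum(lnv * W)
      dC[k, s] <- sum(W * lnW)
    }
  }
  structure(list(q = q, scales = skeleton$scales[scale_index],
                 scale_index = scale_index, lnZ = lnZ, h_canon = hC,
                 D_canon = dC, N_a = nmag, value_mode = value_mode,
                 voices = skeleton$voices,
                 mags = lapply(sets, function(d) d$mag),
                 times = lapply(sets, function(d) d$time),
                 dt = skeleton$dt),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d q values x %d scales, N_a = %d..%d (%s mode)\n",
              length(x$q), length(x$scales), min(x$N_a), max(x$N_a), x$value_mode))
  invisible(x)
}

#' Scaling exponents tau(q), h(q), D(q) from log-log regression
#'
#' Per moment order q, unweighted least-squares slope of ln Z(q, a) vs ln a
#' gives tau(q); slopes of the canonical h(q, a) and D(q, a) vs ln a give the
#' parametric singularity-spectrum curve (h(q), D(q)). Since adjacent voices
#' of the same octave are strongly dependent, regression standard errors are
#' inflated by sqrt(V) (V voices per octave).
#'
#' @param ensemble a `partition_ensemble`.
#' @param fit_range length-2 numeric: scale range (samples) used for the
#'   fits; must lie inside the analyzed scales and contain >= 4 scale points.
#' @return an object of class `scaling_fit`: `q`, `tau`, `tau_se`, `h`,
#'   `h_se`, `D`, `D_se`, `fit_range`, `n_scales`, `r_squared`.
#' @export
fit_scaling_exponents <- function(ensemble, fit_range) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  a <- ensemble$scales
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    stop("invalid-parameter: fit_range must be (a_min, a_max)", call. = FALSE)
  if (fit_range[1] < min(a) / 1.0001 || fit_range[2] > max(a) * 1.0001)
    stop("invalid-parameter: fit_range extends beyond the analyzed scales",
         call. = FALSE)
  sel <- a >= fit_range[1] & a <= fit_range[2]
  if (sum(sel) < 4L)
    stop("invalid-parameter: fewer than 4 scale points in fit_range", call. = FALSE)
  la <- log(a[sel])
  V <- if (is.na(ensemble$voices)) 1 else ensemble$voices
  infl <- sqrt(max(1, V))
  slope_fit <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 4L) return(c(NA_real_, NA_real_, NA_real_))
    f <- stats::lm.fit(cbind(1, la[ok]), y[ok])
    res <- f$residuals
    nn <- sum(ok)
    sxx <- sum((la[ok] - mean(la[ok]))^2)
    se <- sqrt(sum(res^2) / max(nn - 2L, 1L) / sxx)
    r2 <- 1 - sum(res^2) / max(sum((y[ok] - mean(y[ok]))^2), .Machine$double.xmin)
    c(f$coefficients[2L], se * infl, r2)
  }
  nq <- length(ensemble$q)
  tau <- h <- D <- tau_se <- h_se <- D_se <- r2 <- numeric(nq)
  for (k in seq_len(nq)) {
    ft <- slope_fit(ensemble$lnZ[k, sel])
    tau[k] <- ft[1]; tau_se[k] <- ft[2]; r2[k] <- ft[3]
    fh <- slope_fit(ensemble$h_canon[k, sel])
    h[k] <- fh[1]; h_se[k] <- fh[2]
    fd <- slope_fit(ensemble$D_canon[k, sel])
    D[k] <- fd[1]; D_se[k] <- fd[2]
  }
  structure(list(q = ensemble$q, tau = tau, tau_se = tau_se,
                 h = h, h_se = h_se, D = D, D_se = D_se,
                 fit_range = fit_range, n_scales = sum(sel),
                 r_squared = r2, value_mode = ensemble$value_mode),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  i0 <- which.min(abs(x$q))
  i2 <- which.min(abs(x$q - 2))
  cat(sprintf("<scaling_fit> q in [%g, %g], fit range a = %g..%g samples (%d scales)\n",
              min(x$q), max(x$q), x$fit_range[1], x$fit_range[2], x$n_scales))
  cat(sprintf("  tau(%g) = %.3f +- %.3f, tau(%g) = %.3f +- %.3f\n",
              x$q[i0], x$tau[i0], x$tau_se[i0], x$q[i2], x$tau[i2], x$tau_se[i2]))
  invisible(x)
}

#' Numeric Legendre transform of tau(q)
#'
#' h(q) = dtau/dq by central differences; D = q h - tau. For a concave tau
#' this is the singularity spectrum D(h) as a curve parametrized by q.
#'
#' @param q moment-order grid (strictly increasing).
#' @param tau tau(q) values.
#' @return data.frame with columns `q`, `h`, `D`.
#' @export
legendre_transform <- function(q, tau) {
  stopifnot(length(q) == length(tau), length(q) >= 3L)
  n <- length(q)
  h <- numeric(n)
  h[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  h[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  if (n > 2L)
    h[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  data.frame(q = q, h = h, D = q * h - tau)
}

#' Singularity spectrum D(h) from a scaling fit
#'
#' Returns the canonical parametric curve (h(q), D(q)) estimated from the
#' slopes of the canonical expectation values (the numerically stable route),
#' together with the direct numeric Legendre transform of the fitted tau(q)
#' as a cross-check (columns `h_leg`, `D_leg`).
#'
#' @param fit a `scaling_fit`.
#' @return data.frame with columns `q`, `h`, `D`, `h_se`, `D_se`, `h_leg`,
#'   `D_leg`.
#' @export
legendre_spectrum <- function(fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  leg <- legendre_transform(fit$q, fit$tau)
  data.frame(q = fit$q, h = fit$h, D = fit$D, h_se = fit$h_se, D_se = fit$D_se,
             h_leg = leg$h, D_leg = leg$D)
}

#' Closed-form quadratic singularity spectrum
#'
#' D(h) = c0 - (h - c1)^2 / (2 c2), the Legendre transform of the log-normal
#' quadratic tau(q) = -c0 + c1 q - c2 q^2/2.
#'
#' @param h Hölder exponent grid.
#' @param c0,c1,c2 quadratic spectrum coefficients (c2 > 0).
#' @return numeric vector D(h).
#' @export
quadratic_dh <- function(h, c0, c1, c2) c0 - (h - c1)^2 / (2 * c2)

#' Quadratic (log-normal) fit of tau(q)
#'
#' Weighted polynomial fit tau(q) = -c0 + c1 q - c2 q^2/2 (+ c3 q^3/6 when
#' `max_order = 3`), with weights 1/stderr^2 when slope standard errors are
#' available. c0 is reported as -tau(0) with its own regression stderr when
#' q = 0 is on the grid (the fractal dimension of the singularity support);
#' c2 is constrained to be >= 0, with the unconstrained value kept in
#' `c2_raw`.
#'
#' @param fit a `scaling_fit`, or any list with numeric `q`, `tau` and
#'   optionally `tau_se`.
#' @param max_order 2 (log-normal) or 3 (adds the skewness term).
#' @return an object of class `quadratic_spectrum`: coefficients `c0`, `c1`,
#'   `c2`, `c3` with standard errors, `c2_raw`, and `method = "moments"`.
#' @export
fit_quadratic_tau <- function(fit, max_order = 2L) {
  q <- fit$q; tau <- fit$tau
  se <- fit$tau_se
  ok <- is.finite(q) & is.finite(tau)
  if (sum(ok) < 5L)
    stop("invalid-parameter: need at least 5 q points", call. = FALSE)
  q <- q[ok]; tau <- tau[ok]
  w <- if (!is.null(se) && all(is.finite(se[ok])) && all(se[ok] > 0))
    1 / se[ok]^2 else rep(1, length(q))
  max_order <- as.integer(max_order)
  if (!max_order %in% c(2L, 3L))
    stop("invalid-parameter: max_order must be 2 or 3", call. = FALSE)
  X <- cbind(1, stats::poly(q, degree = max_order, raw = TRUE))
  XtWX <- crossprod(X * sqrt(w))
  Vi <- solve(XtWX)
  cf <- drop(Vi %*% crossprod(X * w, tau))
  # when slope stderr per q is available, take it as the known sampling sd of
  # tau(q). Errors of tau at different q are estimated from the same scales
  # and line sets, hence strongly dependent: combine the independent-error
  # GLS variance (X' W X)^-1 with a fully-correlated one-factor term (the
  # coefficients obtained by projecting the stderr pattern itself).
  cse <- if (!is.null(se) && all(is.finite(se[ok])) && all(se[ok] > 0)) {
    corr_part <- abs(drop(Vi %*% crossprod(X * w, se[ok])))
    sqrt(diag(Vi) + corr_part^2)
  } else {
    m0 <- stats::lm.wfit(X, tau, w)
    s2 <- sum(w * m0$residuals^2) / max(length(q) - ncol(X), 1L)
    sqrt(diag(Vi) * s2)
  }
  c0 <- -cf[[1]]; c0_se <- cse[[1]]
  if (any(q == 0) && !is.null(se) && is.finite(se[which(fit$q == 0)[1]])) {
    i0 <- which(fit$q == 0)[1]
    c0 <- -fit$tau[i0]; c0_se <- fit$tau_se[i0]
  }
  c2_raw <- -2 * cf[[3]]
  structure(list(c0 = c0, c0_se = c0_se,
                 c1 = cf[[2]], c1_se = cse[[2]],
                 c2 = max(0, c2_raw), c2_raw = c2_raw, c2_se = 2 * cse[[3]],
                 c3 = if (max_order == 3L) 6 * cf[[4]] else 0,
                 c3_se = if (max_order == 3L) 6 * cse[[4]] else NA_real_,
                 method = "moments"),
            class = "quadratic_spectrum")
}

#' @export
print.quadratic_spectrum <- function(x, ...) {
  cat(sprintf("<quadratic_spectrum> [%s] c0 = %.3f +- %.3f, c1 = %.3f +- %.3f, c2 = %.3f +- %.3f\n",
              x$method, x$c0, x$c0_se, x$c1, x$c1_se, x$c2, x$c2_se))
  if (is.finite(x$c3_se))
    cat(sprintf("  c3 = %.4f +- %.4f\n", x$c3, x$c3_se))
  invisible(x)
}

#' Log-normal propagator kernel between two scales
#'
#' Under the quadratic tau(q) model the magnitude pdf at a fine scale a is
#' the coarse-scale pdf (at a' > a) convolved with a Gaussian kernel of mean
#' c1 ln(a/a') and variance c2 ln(a'/a). The monofractal case is the c2 = 0
#' (delta-kernel) limit with c1 = H.
#'
#' @param c1,c2 log-normal spectrum coefficients (c2 >= 0).
#' @return an object of class `propagator_model`.
#' @export
propagator_model <- function(c1, c2) {
  if (!is.finite(c2) || c2 < 0)
    stop("invalid-parameter: propagator variance coefficient c2 must be >= 0",
         call. = FALSE)
  structure(list(c1 = c1, c2 = c2), class = "propagator_model")
}

#' Propagator-based pdf collapse check
#'
#' For each pair of analyzed scales (a < a'), predicts the magnitude (ln |T|)
#' distribution at the finer scale by convolving the empirical coarse-scale
#' distribution with the model kernel, and reports the Kolmogorov-Smirnov
#' distance between predicted and observed fine-scale distributions. A good
#' collapse (small distances with the fitted c1, c2, clearly smaller than
#' with a wrong kernel) is the signature that one propagation law rules the
#' statistics across scales.
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param model a [propagator_model()].
#' @param scale_index integer vector (>= 2) of scale positions to compare;
#'   each must carry at least `min_n` magnitudes.
#' @param value_mode passed to [line_set_at_scale()].
#' @param min_n minimum magnitudes per scale (default 200).
#' @return data.frame with one row per (fine, coarse) pair: `a_fine`,
#'   `a_coarse`, `ks_dist`, `n_fine`, `n_coarse`.
#' @export
pdf_collapse <- function(skeleton, model, scale_index,
                         value_mode = c("value", "sup"), min_n = 200L) {
  stopifnot(inherits(skeleton, "wtmm_skeleton"), inherits(model, "propagator_model"))
  value_mode <- match.arg(value_mode)
  if (length(scale_index) < 2L)
    stop("invalid-parameter: need at least 2 scales", call. = FALSE)
  scale_index <- sort(as.integer(scale_index))
  mags <- lapply(scale_index, function(s)
    log(line_set_at_scale(skeleton, s, value_mode = value_mode)$mag))
  nn <- vapply(mags, length, integer(1))
  if (any(nn < min_n))
    stop(sprintf("invalid-input: need >= %d magnitudes per scale (got %d)",
                 min_n, min(nn)), call. = FALSE)
  a <- skeleton$scales[scale_index]
  out <- NULL
  for (i in seq_along(scale_index)[-length(scale_index)]) {
    for (j in (i + 1):length(scale_index)) {
      m_f <- mags[[i]]; m_c <- mags[[j]]             # a[i] < a[j]
      mu <- model$c1 * log(a[i] / a[j])
      sg <- sqrt(model$c2 * log(a[j] / a[i]))
      xs <- sort(m_f)
      emp <- seq_along(xs) / length(xs)
      pred <- vapply(xs, function(x) {
        if (sg > 0) mean(stats::pnorm((x - m_c - mu) / sg))
        else mean(m_c + mu <= x)
      }, numeric(1))
      ks <- max(abs(emp - pred), abs(emp - 1 / length(xs) - pred))
      out <- rbind(out, data.frame(a_fine = a[i], a_coarse = a[j],
                                   ks_dist = ks, n_fine = length(m_f),
                                   n_coarse = length(m_c)))
    }
  }
  out
}
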