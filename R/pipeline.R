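#' Configuration of an end-to-end multifractal analysis run
#'
#' Bundles every tunable of the pipeline: input signal (a trace, a synthetic
#' spec, or a delimited-text file), the impulse-energy preprocessing switch,
#' analyzing-wavelet orders, the scale grid and fit range, the moment grid,
#' and the scales at which the two-point magnitude correlation is evaluated.
#' Robustness protocol default: analyze with wavelet orders 2 and 3 and
#' require their spectra to agree.
#'
#' @param input a [signal_trace()], an `fbm_spec` / `cascade_spec` /
#'   `fixture_spec` / `egm_spec`, or a file path readable by
#'   [read_signal_trace()].
#' @param channel channel for multi-channel input files.
#' @param preprocess `"energy"` to apply [impulse_energy()] (for recorded
#'   potential differences), `"none"` to analyze the input as is (for
#'   synthetic signals that already have the statistics of interest).
#' @param oversample oversampling factor for the energy derivative
#'   (default 10).
#' @param scale_range length-2 numeric, analyzed scales in samples.
#' @param voices voices per octave of the scale grid.
#' @param wavelet_orders subset of 1:3; spectra are computed per order.
#' @param fit_range length-2 numeric, scale range of the log-log fits; must
#'   lie inside `scale_range`.
#' @param q moment-order grid.
#' @param value_mode `"value"` or `"sup"` WTMM magnitudes.
#' @param corr_scales scales (samples) at which C(a, dt) is computed; each is
#'   snapped to the nearest grid scale.
#' @param seed integer seed (used when `input` is a stochastic spec).
#' @param out_dir optional output directory for [write_report()].
#' @param plots write diagnostic plots in [write_report()] (default FALSE).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, channel = 1L,
                       preprocess = c("none", "energy"), oversample = 10,
                       scale_range = c(2^5, 2^13), voices = 8L,
                       wavelet_orders = c(2L, 3L),
                       fit_range = c(2^9, 2^13),
                       q = seq(-1, 5, by = 0.25),
                       value_mode = c("value", "sup"),
                       corr_scales = c(2^9, 2^10),
                       seed = 1L, out_dir = NULL, plots = FALSE) {
  preprocess <- match.arg(preprocess)
  value_mode <- match.arg(value_mode)
  cfg_fail <- function(msg) stop(structure(
    class = c("config_error", "error", "condition"),
    list(message = paste0("invalid-config: ", msg), call = NULL)))
  if (!all(wavelet_orders %in% 1:3)) cfg_fail("wavelet_orders must be within 1..3")
  if (length(scale_range) != 2L || scale_range[1] >= scale_range[2])
    cfg_fail("scale_range must be (a_min, a_max)")
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    cfg_fail("fit_range must be (a_min, a_max)")
  if (fit_range[1] < scale_range[1] || fit_range[2] > scale_range[2])
    cfg_fail("fit_range must lie inside scale_range")
  structure(list(input = input, channel = channel, preprocess = preprocess,
                 oversample = oversample, scale_range = scale_range,
                 voices = as.integer(voices),
                 wavelet_orders = as.integer(wavelet_orders),
                 fit_range = fit_range, q = q, value_mode = value_mode,
                 corr_scales = corr_scales, seed = as.integer(seed),
                 out_dir = out_dir, plots = isTRUE(plots)),
            class = "run_config")
}

resolve_input <- function(config) {
  inp <- config$input
  if (inherits(inp, "signal_trace")) return(inp)
  if (inherits(inp, c("fbm_spec", "cascade_spec", "fixture_spec", "egm_spec"))) {
    inp$seed <- config$seed
    return(switch(class(inp)[1],
                  fbm_spec = gen_fbm(inp),
                  cascade_spec = gen_cascade_signal(inp),
                  fixture_spec = gen_fixture(inp),
                  egm_spec = gen_surrogate_egm(inp)))
  }
  if (is.character(inp) && length(inp) == 1L) {
    if (!file.exists(inp))
      stop(sprintf("invalid-input: cannot read '%s'", inp), call. = FALSE)
    return(read_signal_trace(inp, channel = config$channel))
  }
  stop("invalid-config: unrecognized input", call. = FALSE)
}

#' Run the full multifractal analysis pipeline
#'
#' Stages: ingest or generate the signal; optional impulse-energy
#' preprocessing; per analyzing-wavelet order: CWT, skeleton, partition
#' functions + scaling fits + quadratic spectrum, magnitude cumulants +
#' slope fits, two-point magnitude correlation + cascade verdict; finally a
#' cross-order robustness comparison of (c0, c1, c2). Fully deterministic
#' given (config, seed).
#'
#' @param config a [run_config()].
#' @return an object of class `wtmm_run`: list with `signal` metadata,
#'   `per_order` results (one entry per wavelet order), `robustness`
#'   (pairwise joint-stderr agreement of the quadratic coefficients), and
#'   `config` echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trace <- resolve_input(config)
  if (config$preprocess == "energy")
    trace <- impulse_energy(trace, target_dt = trace$dt / config$oversample)

  scales <- scale_grid(config$scale_range[1], config$scale_range[2],
                       voices = config$voices)
  per_order <- list()
  for (N in config$wavelet_orders) {
    plane <- cwt_transform(trace, scales, order = N, voices = config$voices)
    skel <- build_skeleton(plane)
    ens <- partition_functions(skel, q = config$q, value_mode = config$value_mode)
    sf <- fit_scaling_exponents(ens, config$fit_range)
    quad <- fit_quadratic_tau(sf)
    cum <- compute_magnitude_cumulants(skel, value_mode = config$value_mode)
    cumfit <- fit_cumulant_slopes(cum, config$fit_range)
    spec_dh <- legendre_spectrum(sf)

    corr <- list()
    for (a0 in config$corr_scales) {
      s_idx <- which.min(abs(log2(skel$scales) - log2(a0)))
      mc <- tryCatch(compute_magnitude_correlation(skel, s_idx,
                                                   value_mode = config$value_mode),
                     error = function(e) e)
      if (!inherits(mc, "error")) {
        v <- assess_cascade_structure(mc, c2 = quad$c2)
        corr[[as.character(skel$scales[s_idx])]] <- list(correlation = mc,
                                                         verdict = v)
      }
    }
    per_order[[paste0("g", N)]] <- list(
      order = N, n_lines = length(skel$lines),
      scaling = sf, quadratic = quad, dh = spec_dh,
      cumulants = cum, cumulant_fit = cumfit, correlation = corr)
  }

  robustness <- NULL
  ords <- names(per_order)
  if (length(ords) >= 2L) {
    for (i in seq_len(length(ords) - 1L)) {
      qa <- per_order[[ords[i]]]$quadratic
      qb <- per_order[[ords[i + 1L]]]$quadratic
      agree <- function(x, y, sx, sy) abs(x - y) <= 2 * sqrt(sx^2 + sy^2)
      robustness <- rbind(robustness, data.frame(
        pair = paste(ords[i], ords[i + 1L], sep = "-"),
        dc0 = qa$c0 - qb$c0, dc1 = qa$c1 - qb$c1, dc2 = qa$c2 - qb$c2,
        c0_agree = agree(qa$c0, qb$c0, qa$c0_se, qb$c0_se),
        c1_agree = agree(qa$c1, qb$c1, qa$c1_se, qb$c1_se),
        c2_agree = agree(qa$c2, qb$c2, qa$c2_se, qb$c2_se)))
    }
  }
  structure(list(signal = list(label = trace$label, n = length(trace$values),
                               dt = trace$dt, preprocess = config$preprocess),
                 per_order = per_order, robustness = robustness,
                 config = config),
            class = "wtmm_run")
}

#' @export
print.wtmm_run <- function(x, ...) {
  cat(sprintf("<wtmm_run> %s (%d samples), orders: %s\n", x$signal$label,
              x$signal$n, paste(names(x$per_order), collapse = ", ")))
  for (nm in names(x$per_order)) {
    qd <- x$per_order[[nm]]$quadratic
    cf <- x$per_order[[nm]]$cumulant_fit
    cat(sprintf("  %s: moments  c0 = %.3f, c1 = %.3f, c2 = %.3f | cumulants c1* = %.3f, c2* = %.3f\n",
                nm, qd$c0, qd$c1, qd$c2, cf$c1, cf$c2))
  }
  invisible(x)
}

# Move an existing file aside (name.1, name.2, ...) instead of clobbering.
version_path <- function(path) {
  if (!file.exists(path)) return(invisible(path))
  k <- 1L
  while (file.exists(paste0(path, ".", k))) k <- k + 1L
  file.rename(path, paste0(path, ".", k))
  invisible(path)
}

#' Write a run report to disk
#'
#' Emits a JSON summary (quadratic coefficients per order and method,
#' robustness table, cascade verdicts, config echo), per-order TSV tables
#' (tau(q) and D(h); cumulant curves; magnitude correlation), and optional
#' base-graphics diagnostic plots. Existing files are versioned
#' (`name.1`, ...), never overwritten.
#'
#' @param run a `wtmm_run` from [run_pipeline()].
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `out_dir`.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(run, out_dir = run$config$out_dir) {
  stopifnot(inherits(run, "wtmm_run"))
  if (is.null(out_dir))
    stop("invalid-parameter: no output directory configured", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("invalid-output: cannot create '%s'", out_dir), call. = FALSE)
  written <- character(0)
  emit <- function(path) { version_path(path); written <<- c(written, path); path }

  summ <- list(signal = run$signal,
               config = list(scale_range = run$config$scale_range,
                             fit_range = run$config$fit_range,
                             voices = run$config$voices,
                             q = range(run$config$q),
                             value_mode = run$config$value_mode,
                             wavelet_orders = run$config$wavelet_orders,
                             seed = run$config$seed),
               robustness = run$robustness,
               per_order = lapply(run$per_order, function(po) list(
                 order = po$order, n_lines = po$n_lines,
                 moments = po$quadratic[c("c0", "c0_se", "c1", "c1_se",
                                          "c2", "c2_se")],
                 cumulants = po$cumulant_fit[c("c0", "c0_se", "c1", "c1_se",
                                               "c2", "c2_se", "c3", "c3_se")],
                 verdicts = lapply(po$correlation, function(cc)
                   cc$verdict[c("verdict", "slope", "slope_se",
                                "expected_slope", "mean_norm_C")]))))
  jp <- emit(file.path(out_dir, "summary.json"))
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA, null = "null")

  for (nm in names(run$per_order)) {
    po <- run$per_order[[nm]]
    tp <- emit(file.path(out_dir, sprintf("tau_%s.tsv", nm)))
    utils::write.table(
      data.frame(q = po$scaling$q, tau = po$scaling$tau,
                 tau_se = po$scaling$tau_se, h = po$dh$h, D = po$dh$D),
      tp, sep = "\t", row.names = FALSE, quote = FALSE)
    cp <- emit(file.path(out_dir, sprintf("cumulants_%s.tsv", nm)))
    cumulants_to_tsv(po$cumulants, cp)
    for (sc in names(po$correlation)) {
      mp <- emit(file.path(out_dir, sprintf("magcorr_%s_a%s.tsv", nm, sc)))
      magnitude_correlation_to_tsv(po$correlation[[sc]]$correlation, mp)
    }
    if (run$config$plots) {
      pp <- emit(file.path(out_dir, sprintf("spectra_%s.png", nm)))
      grDevices::png(pp, width = 900, height = 600)
      graphics::par(mfrow = c(1, 2))
      graphics::plot(po$scaling$q, po$scaling$tau, xlab = "q", ylab = "tau(q)",
                     main = paste("tau(q),", nm))
      qq <- po$scaling$q
      graphics::lines(qq, tau_from_coefficients(po$quadratic, qq), col = 2)
      graphics::plot(po$dh$h, po$dh$D, xlab = "h", ylab = "D(h)",
                     main = "singularity spectrum", type = "b")
      grDevices::dev.off()
    }
  }
  invisible(written)
}
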