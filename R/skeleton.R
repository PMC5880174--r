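#' Detect wavelet-transform modulus maxima at one scale
#'
#' Strict local maxima of |T(t, a)| over time among valid (non-boundary)
#' points: |T[i]| > |T[i-1]| and |T[i]| >= |T[i+1]|, so equal-valued plateaus
#' keep their leftmost index (deterministic tie-break).
#'
#' @param plane a `wavelet_plane` from [cwt_transform()].
#' @param scale_index column index into `plane$scales`.
#' @param rel_floor maxima with modulus below `rel_floor * max|T(., a)|` are
#'   ignored: they are FFT round-off, not signal structure (default 1e-9).
#' @return integer vector of time indices (possibly empty).
#' @export
detect_maxima_at_scale <- function(plane, scale_index, rel_floor = 1e-9) {
  stopifnot(inherits(plane, "wavelet_plane"))
  s <- as.integer(scale_index)
  if (s < 1L || s > length(plane$scales))
    stop("invalid-parameter: scale_index outside the analyzed grid", call. = FALSE)
  x <- abs(plane$coefficients[, s])
  ok <- plane$valid_mask[, s]
  if (!any(ok)) return(integer(0))
  floor_val <- rel_floor * max(x[ok])
  n <- length(x)
  i <- 2:(n - 1L)
  hit <- x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > floor_val & ok[i]
  which(hit) + 1L
}

#' Build the WTMM skeleton by chaining maxima across scales
#'
#' Maxima are chained from the finest to the coarsest scale by mutual
#' nearest-neighbour association within a window `max(2, a*(2^(1/V)-1)*kappa)`
#' samples (maxima of Gaussian-wavelet transforms drift at most O(a) per
#' octave). When two lines compete for one coarse maximum the closer one
#' continues and the other terminates (lines merge as scale grows); coarse
#' maxima left unmatched seed new lines. Lines spanning fewer than
#' `min_length` scale samples are discarded as unable to support a slope
#' estimate.
#'
#' @param plane a `wavelet_plane`.
#' @param kappa chaining window multiplier (default 6).
#' @param max_gap number of consecutive voice steps a line may go unmatched
#'   before it is terminated (default 2). Modulus maxima of noisy signals can
#'   vanish over a fraction of an octave and reappear; bridged scales take
#'   the line's held time index.
#' @param min_length minimum number of scales a line must span (default 3).
#' @return an object of class `wtmm_skeleton`: list with `lines` (each a list
#'   with integer `birth`, `death` scale indices and per-scale `time`,
#'   `modulus`, `value` vectors), `scales`, `voices`, `order`, `dt`,
#'   `n_times`, and `alive` (list: line ids present at each scale).
#' @export
build_skeleton <- function(plane, kappa = 6, max_gap = 2L, min_length = 3L) {
  stopifnot(inherits(plane, "wavelet_plane"))
  S <- length(plane$scales)
  if (S < 2L)
    stop("invalid-input: need at least 2 scales to chain maxima", call. = FALSE)
  V <- if (is.na(plane$voices)) 8 else plane$voices

  line_time <- list(); line_birth <- integer(0)
  active_id <- integer(0); active_pos <- integer(0); active_miss <- integer(0)

  for (s in seq_len(S)) {
    mx <- detect_maxima_at_scale(plane, s)
    matched_line <- integer(0)
    matched_max <- integer(0)
    if (s > 1L && length(active_id) && length(mx)) {
      win <- max(2, plane$scales[s] * (2^(1 / V) - 1) * kappa)
      # all (line, maximum) candidate pairs within the window, then greedy
      # assignment by increasing distance: a line whose nearest maximum is
      # claimed by a closer line can still take its next-nearest candidate
      lo <- findInterval(active_pos - win, mx) + 1L
      hi <- findInterval(active_pos + win, mx)
      nc <- pmax(hi - lo + 1L, 0L)
      if (any(nc > 0L)) {
        p_line <- rep.int(seq_along(active_pos), nc)
        p_max <- unlist(lapply(which(nc > 0L), function(i) lo[i]:hi[i]),
                        use.names = FALSE)
        p_dist <- abs(active_pos[p_line] - mx[p_max])
        ord <- order(p_dist, active_id[p_line], p_max)
        taken_max <- logical(length(mx))
        taken_line <- logical(length(active_pos))
        for (ii in ord) {
          li <- p_line[ii]; mj <- p_max[ii]
          if (!taken_line[li] && !taken_max[mj]) {
            taken_line[li] <- TRUE
            taken_max[mj] <- TRUE
            matched_line <- c(matched_line, li)
            matched_max <- c(matched_max, mj)
          }
        }
      }
    }
    # continue matched lines, bridging any pending gap at the held position
    new_active_id <- integer(0); new_active_pos <- integer(0)
    new_active_miss <- integer(0)
    if (length(matched_line)) {
      ids <- active_id[matched_line]
      pos <- mx[matched_max]
      for (k in seq_along(matched_line)) {
        gap <- active_miss[matched_line[k]]
        if (gap > 0L)
          line_time[[ids[k]]] <- c(line_time[[ids[k]]],
                                   rep.int(active_pos[matched_line[k]], gap))
        line_time[[ids[k]]] <- c(line_time[[ids[k]]], pos[k])
      }
      new_active_id <- ids
      new_active_pos <- pos
      new_active_miss <- integer(length(ids))
    }
    # unmatched lines stay pending for up to max_gap voice steps
    if (s > 1L && length(active_id)) {
      pend <- setdiff(seq_along(active_id), matched_line)
      pend <- pend[active_miss[pend] < max_gap]
      if (length(pend)) {
        new_active_id <- c(new_active_id, active_id[pend])
        new_active_pos <- c(new_active_pos, active_pos[pend])
        new_active_miss <- c(new_active_miss, active_miss[pend] + 1L)
      }
    }
    # unmatched maxima seed new lines
    fresh <- if (s == 1L) mx else mx[!seq_along(mx) %in% matched_max]
    if (length(fresh)) {
      ids <- length(line_time) + seq_along(fresh)
      for (k in seq_along(fresh)) line_time[[ids[k]]] <- fresh[k]
      line_birth <- c(line_birth, rep.int(s, length(fresh)))
      new_active_id <- c(new_active_id, ids)
      new_active_pos <- c(new_active_pos, fresh)
      new_active_miss <- c(new_active_miss, integer(length(fresh)))
    }
    ord2 <- order(new_active_pos, new_active_id)
    active_id <- new_active_id[ord2]
    active_pos <- new_active_pos[ord2]
    active_miss <- new_active_miss[ord2]
  }

  lines <- vector("list", length(line_time))
  keep <- logical(length(line_time))
  for (id in seq_along(line_time)) {
    tt <- line_time[[id]]
    birth <- line_birth[id]
    death <- birth + length(tt) - 1L
    if (length(tt) < min_length) next
    sidx <- birth:death
    vals <- plane$coefficients[cbind(tt, sidx)]
    lines[[id]] <- list(birth = birth, death = death, time = tt,
                        modulus = abs(vals), value = vals)
    keep[id] <- TRUE
  }
  lines <- lines[keep]
  alive <- vector("list", S)
  for (li in seq_along(lines)) {
    l <- lines[[li]]
    for (s in l$birth:l$death) alive[[s]] <- c(alive[[s]], li)
  }
  structure(list(lines = lines, scales = plane$scales, voices = plane$voices,
                 order = plane$order, dt = plane$dt,
                 n_times = nrow(plane$coefficients), alive = alive),
            class = "wtmm_skeleton")
}

#' @export
print.wtmm_skeleton <- function(x, ...) {
  cat(sprintf("<wtmm_skeleton> %d maxima lines over %d scales (g^(%d))\n",
              length(x$lines), length(x$scales), x$order))
  invisible(x)
}

#' The line set L(a): lines persisting down to the finest analyzed scale
#'
#' A line belongs to L(a) if it has a point at every analyzed scale a' <= a,
#' i.e. it was born at the finest grid scale and is still alive at a. Per
#' line, returns either the WTMM magnitude at a (`"value"`) or the supremum
#' of the modulus along the line at scales <= a (`"sup"`, more stable for
#' negative moment orders).
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param scale_index scale position in `skeleton$scales`.
#' @param value_mode `"value"` or `"sup"`.
#' @return data.frame with columns `line`, `time` (sample index at a),
#'   `mag` (WTMM magnitude).
#' @export
line_set_at_scale <- function(skeleton, scale_index,
                              value_mode = c("value", "sup")) {
  stopifnot(inherits(skeleton, "wtmm_skeleton"))
  value_mode <- match.arg(value_mode)
  s <- as.integer(scale_index)
  if (s < 1L || s > length(skeleton$scales))
    stop("invalid-parameter: scale_index outside the analyzed grid", call. = FALSE)
  ids <- skeleton$alive[[s]]
  ids <- ids[vapply(skeleton$lines[ids], function(l) l$birth == 1L, logical(1))]
  if (!length(ids))
    return(data.frame(line = integer(0), time = integer(0), mag = numeric(0)))
  tm <- integer(length(ids)); mg <- numeric(length(ids))
  for (k in seq_along(ids)) {
    l <- skeleton$lines[[ids[k]]]
    off <- s - l$birth + 1L
    tm[k] <- l$time[off]
    mg[k] <- if (value_mode == "sup") max(l$modulus[1:off]) else l$modulus[off]
  }
  data.frame(line = ids, time = tm, mag = mg)
}

#' Scaling exponent of one maxima line
#'
#' Least-squares slope of log2 |T| vs log2 a along a line, the direct reading
#' of the Hölder exponent of the singularity the line points to.
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param line line index into `skeleton$lines`.
#' @param a_min,a_max optional scale range (samples) for the fit.
#' @return list with `slope` (the Hölder estimate), `stderr`, `n`.
#' @export
line_exponent <- function(skeleton, line, a_min = NULL, a_max = NULL) {
  stopifnot(inherits(skeleton, "wtmm_skeleton"))
  l <- skeleton$lines[[line]]
  sidx <- l$birth:l$death
  a <- skeleton$scales[sidx]
  sel <- rep(TRUE, length(a))
  if (!is.null(a_min)) sel <- sel & a >= a_min
  if (!is.null(a_max)) sel <- sel & a <= a_max
  if (sum(sel) < 3L)
    stop("invalid-parameter: fewer than 3 points in the fit range", call. = FALSE)
  x <- log2(a[sel]); y <- log2(l$modulus[sel])
  fit <- stats::lm.fit(cbind(1, x), y)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(fit$residuals^2) / max(sum(sel) - 2L, 1L) / sxx)
  list(slope = unname(fit$coefficients[2L]), stderr = se, n = sum(sel))
}

#' Serialize a skeleton to TSV
#'
#' One row per (line, scale) point: `line_id`, `scale` (samples), `time_s`,
#' `modulus`. Suitable for plotting the skeleton.
#'
#' @param skeleton a `wtmm_skeleton`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
skeleton_to_tsv <- function(skeleton, path) {
  rows <- lapply(seq_along(skeleton$lines), function(li) {
    l <- skeleton$lines[[li]]
    data.frame(line_id = li, scale = skeleton$scales[l$birth:l$death],
               time_s = (l$time - 1L) * skeleton$dt, modulus = l$modulus)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
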