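# Oscillation metrics: peak detection, period and phase extraction, and the
# mean-field synchronization index R_syn.

#' Locate oscillation peaks
#'
#' Local maxima with sub-grid timing by quadratic interpolation through the
#' three samples around each maximum. Maxima whose rise above the higher of
#' the two adjacent minima is below `min_prominence_frac` of the series'
#' peak-to-trough range are discarded (square-wave forcing can leave small
#' kinks on the flanks).
#'
#' @param value Numeric series.
#' @param time Matching time grid, h.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   series range.
#' @return A tibble with `time` (interpolated peak times, h) and `value`;
#'   zero rows (with attribute `oscillatory = FALSE`) for a flat series.
#' @export
#' @examples
#' t <- seq(0, 96, 0.1)
#' find_peaks(sin(2 * pi * t / 24), t)$time  # 6, 30, 54, 78
find_peaks <- function(value, time, min_prominence_frac = 0.05) {
  stopifnot(length(value) == length(time), length(value) >= 3)
  rng <- diff(range(value))
  flat <- rng < max(1e-12, 1e-9 * max(abs(value)))
  if (flat) {
    out <- tibble::tibble(time = numeric(0), value = numeric(0))
    attr(out, "oscillatory") <- FALSE
    return(out)
  }
  s <- sign(diff(value))
  # carry the previous non-zero slope sign through flat samples
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  turn <- diff(s)
  imax <- which(turn < 0) + 1L
  imin <- which(turn > 0) + 1L
  if (!length(imax)) {
    out <- tibble::tibble(time = numeric(0), value = numeric(0))
    attr(out, "oscillatory") <- FALSE
    return(out)
  }
  thr <- min_prominence_frac * rng
  keep <- vapply(imax, function(i) {
    left <- imin[imin < i]
    right <- imin[imin > i]
    vleft <- if (length(left)) value[max(left)] else min(value[seq_len(i)])
    vright <- if (length(right)) value[min(right)] else
      min(value[i:length(value)])
    (value[i] - max(vleft, vright)) >= thr
  }, logical(1))
  imax <- imax[keep]
  pt <- vapply(imax, function(i) {
    if (i <= 1L || i >= length(value)) return(time[i])
    y0 <- value[i - 1]; y1 <- value[i]; y2 <- value[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom >= 0) return(time[i])
    delta <- 0.5 * (y0 - y2) / denom
    time[i] + delta * (time[i + 1] - time[i - 1]) / 2
  }, numeric(1))
  pv <- value[imax]
  out <- tibble::tibble(time = pt, value = pv)
  attr(out, "oscillatory") <- TRUE
  out
}

# trailing run of peaks whose successive inter-peak intervals vary < tol
.steady_peaks <- function(peak_times, tol = 0.02) {
  n <- length(peak_times)
  if (n < 3) return(peak_times)
  d <- diff(peak_times)
  k <- length(d)
  while (k > 1 && abs(d[k - 1] - d[k]) / d[k] < tol) k <- k - 1
  peak_times[k:n]
}

#' Oscillation period
#'
#' Mean spacing of successive peaks during the steady oscillation stage
#' (the trailing stretch in which successive inter-peak intervals vary by
#' less than 2%).
#'
#' @inheritParams find_peaks
#' @param burn_in Initial span to discard, h.
#' @return Period in h, or `NA` (with a warning) for a non-oscillatory
#'   series.
#' @export
period_of <- function(value, time, burn_in = 0,
                      min_prominence_frac = 0.05) {
  sel <- time >= burn_in
  pk <- find_peaks(value[sel], time[sel], min_prominence_frac)
  if (nrow(pk) < 2) {
    warning("series is non-oscillatory; period undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(diff(.steady_peaks(pk$time)))
}

# circular mean / sd of clock-time values on [0, period)
.circ_mean <- function(x, period = 24) {
  a <- 2 * pi * x / period
  (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi) * period) %% period
}
.circ_sd <- function(x, period = 24) {
  a <- 2 * pi * x / period
  R <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  sqrt(pmax(-2 * log(R), 0)) / (2 * pi) * period
}

#' Oscillation phase
#'
#' Circular mean, over steady-stage peaks, of the lag between each peak and
#' the most recent reference onset, in \[0, `period`). The reference is the
#' warm-phase onset (ZT0) by default; pass `reference = 12` (or use
#' [zt_reference()]) to measure against the cold onset or a reversed
#' pattern.
#'
#' @inheritParams period_of
#' @param reference Clock time of the reference onset within the zeitgeber
#'   cycle, h.
#' @param period Zeitgeber period, h.
#' @param stability_tol Flag the series unentrained (NA with a warning)
#'   when the circular spread of per-cycle phases exceeds this, h; `Inf`
#'   disables the check.
#' @return Phase in \[0, `period`) h, or `NA`.
#' @export
#' @examples
#' t <- seq(0, 240, 0.1)
#' phase_of(sin(2 * pi * (t - 5) / 24), t)  # peaks 5 h after warm onset
phase_of <- function(value, time, reference = 0, period = 24, burn_in = 0,
                     stability_tol = 0.5, min_prominence_frac = 0.05) {
  sel <- time >= burn_in
  pk <- find_peaks(value[sel], time[sel], min_prominence_frac)
  if (nrow(pk) < 1) {
    warning("series is non-oscillatory; phase undefined", call. = FALSE)
    return(NA_real_)
  }
  ph <- (.steady_peaks(pk$time) - reference) %% period
  if (length(ph) > 1 && .circ_sd(ph, period) > stability_tol) {
    warning("phase is not cycle-stable; flagged unentrained",
            call. = FALSE)
    return(NA_real_)
  }
  .circ_mean(ph, period)
}

#' Reference onset for phase measurement
#'
#' Clock time (within a 24 h cycle anchored at global time 0) of the warm
#' or cold onset of a pattern orientation: the normal pattern is warm on
#' ZT 0-12 and cold on ZT 12-24; the reversed pattern is its 12 h
#' translate.
#'
#' @param orientation `"normal"` or `"reversed"`.
#' @param edge `"warm"` (the phase reference used throughout) or `"cold"`.
#' @param period Cycle length, h.
#' @return Onset time within the cycle, h.
#' @export
zt_reference <- function(orientation = c("normal", "reversed"),
                         edge = c("warm", "cold"), period = 24) {
  orientation <- match.arg(orientation)
  edge <- match.arg(edge)
  swap <- (orientation == "reversed") != (edge == "cold")
  if (swap) period / 2 else 0
}

#' Wrap a phase difference
#'
#' Maps a phase difference onto \[-period/2, period/2), so an exact
#' antiphase shift reports as -12 h (a phase advance) for a 24 h cycle.
#'
#' @param x Phase difference(s), h.
#' @param period Cycle length, h.
#' @return Wrapped difference(s), h.
#' @export
#' @examples
#' phase_shift(17 - 5)  # -12
phase_shift <- function(x, period = 24) {
  ((x + period / 2) %% period) - period / 2
}

#' Synchronization index R_syn
#'
#' The variance over time of the ensemble mean field divided by the mean
#' over cells of each cell's variance over time. Identical cells give
#' exactly 1; uniformly dispersed phases give values near 0; the index is
#' invariant to a common affine rescaling of every cell's series.
#'
#' @param x A `clock_ensemble` or a cells x time numeric matrix.
#' @param component Component name (ensembles only).
#' @param window `c(t0, t1)` time window, h; default the whole grid.
#' @param time Time grid for matrix input.
#' @return R_syn in \[0, 1\], or `NA` (with a warning) when every cell is
#'   constant over the window and the index is undefined.
#' @export
#' @examples
#' t <- seq(0, 96, 0.1)
#' m <- rbind(sin(2 * pi * t / 24), sin(2 * pi * t / 24))
#' r_syn(m, time = t)  # 1
r_syn <- function(x, component = "PerCry_mRNA", window = NULL,
                  time = NULL) {
  if (inherits(x, "clock_ensemble")) {
    m <- .ens_component(x, component)
    time <- x$time_h
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(window)) {
    if (is.null(time)) stop("`time` is required with `window`",
                            call. = FALSE)
    sel <- time >= window[1] & time <= window[2]
    if (!any(sel)) stop("window contains no samples", call. = FALSE)
    m <- m[, sel, drop = FALSE]
  }
  if (nrow(m) < 2) stop("R_syn needs at least 2 cells", call. = FALSE)
  mf <- colMeans(m)
  num <- mean(mf^2) - mean(mf)^2
  den <- mean(rowMeans(m^2) - rowMeans(m)^2)
  if (den <= 1e-12 * max(1, mean(m)^2)) {
    warning("all cells constant over the window; R_syn undefined",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Windowed R_syn trace
#'
#' R_syn evaluated in consecutive windows (24 h by default, the resolution
#' used for shift-schedule adaptation; 720 h for the slow validation
#' trace).
#'
#' @inheritParams r_syn
#' @param window_h Window length, h.
#' @param step_h Step between window starts, h.
#' @param from,to Span covered, h; defaults to the full grid.
#' @return A tibble with `window_start_h`, `window_mid_h`, `r_syn`.
#' @export
r_syn_windowed <- function(x, component = "PerCry_mRNA", window_h = 24,
                           step_h = window_h, from = NULL, to = NULL,
                           time = NULL) {
  if (inherits(x, "clock_ensemble")) {
    time <- x$time_h
    m <- .ens_component(x, component)
  } else {
    m <- as.matrix(x)
  }
  if (is.null(from)) from <- min(time)
  if (is.null(to)) to <- max(time)
  starts <- seq(from, to - window_h, by = step_h)
  vals <- vapply(starts, function(s) {
    suppressWarnings(r_syn(m, window = c(s, s + window_h), time = time))
  }, numeric(1))
  tibble::tibble(window_start_h = starts,
                 window_mid_h = starts + window_h / 2,
                 r_syn = vals)
}

#' Per-cell synchronization report
#'
#' Phases and periods of every cell plus the ensemble mean field, and the
#' synchronization index, for one component over a window.
#'
#' @param ensemble A `clock_ensemble`.
#' @param component Component name.
#' @param window `c(t0, t1)` window, h; defaults to burn-in to end.
#' @param burn_in Span discarded before metrics, h.
#' @param reference Phase reference onset (see [zt_reference()]), h.
#' @param period Zeitgeber period used for phase wrapping, h.
#' @return A `sync_report` (list) with `per_cell` tibble, ensemble phase
#'   and period, `r_syn`, and the window. [tidy()] returns the per-cell
#'   table; [glance()] the one-row summary.
#' @export
sync_report <- function(ensemble, component = "PerCry_mRNA",
                        window = NULL, burn_in = 480, reference = 0,
                        period = 24) {
  m <- .ens_component(ensemble, component)
  time <- ensemble$time_h
  if (is.null(window)) window <- c(burn_in, max(time))
  sel <- time >= window[1] & time <= window[2]
  tt <- time[sel]
  per_cell <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, sel]
    tibble::tibble(
      cell = i,
      period_h = suppressWarnings(period_of(v, tt)),
      phase_h = suppressWarnings(
        phase_of(v, tt, reference = reference, period = period,
                 stability_tol = Inf)))
  })
  avg <- colMeans(m[, sel, drop = FALSE])
  structure(list(
    component = component, window = window,
    per_cell = per_cell,
    ensemble_period_h = suppressWarnings(period_of(avg, tt)),
    ensemble_phase_h = suppressWarnings(
      phase_of(avg, tt, reference = reference, period = period,
               stability_tol = Inf)),
    r_syn = suppressWarnings(r_syn(m[, sel, drop = FALSE]))),
    class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf(
    "<sync_report> %s over [%g, %g] h: R_syn = %.3f, ensemble period %.2f h, phase %.2f h\n",
    x$component, x$window[1], x$window[2], x$r_syn, x$ensemble_period_h,
    x$ensemble_phase_h))
  invisible(x)
}

#' @export
tidy.sync_report <- function(x, ...) x$per_cell

#' @export
glance.sync_report <- function(x, ...) {
  tibble::tibble(component = x$component,
                 window_start_h = x$window[1], window_end_h = x$window[2],
                 r_syn = x$r_syn,
                 ensemble_period_h = x$ensemble_period_h,
                 ensemble_phase_h = x$ensemble_phase_h,
                 phase_sd_h = .circ_sd(stats::na.omit(x$per_cell$phase_h)),
                 period_sd_h = stats::sd(x$per_cell$period_h, na.rm = TRUE))
}
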