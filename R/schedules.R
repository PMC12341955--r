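# Temperature zeitgeber schedules: square-wave patterns, constant segments,
# and alternating shift schedules ("N-n1:n2" grammar).

#' Square-wave temperature pattern
#'
#' A periodic square wave with mean `mean`, peak-to-trough amplitude
#' `amplitude`, period `period` and a warm fraction of the cycle. The
#' "normal" orientation is warm on the first `warm_fraction` of each cycle
#' (warm on ZT 0-12 h for the defaults); "reversed" is its half-period
#' translate (cold on ZT 0-12 h). Zeitgeber time is anchored to global
#' simulation time 0.
#'
#' @param mean Cycle mean temperature, degC.
#' @param amplitude Peak-to-trough amplitude, degC (warm = mean +
#'   amplitude/2, cold = mean - amplitude/2).
#' @param period Cycle length, h.
#' @param warm_fraction Fraction of the cycle spent warm, in (0, 1).
#' @param orientation `"normal"` or `"reversed"`.
#' @return A `temp_pattern` object.
#' @export
#' @examples
#' temp_pattern()                          # W12/C12 37 +/- 1.5 degC
#' temp_pattern(orientation = "reversed")  # 12 h translate
temp_pattern <- function(mean = 37, amplitude = 3, period = 24,
                         warm_fraction = 0.5,
                         orientation = c("normal", "reversed")) {
  orientation <- match.arg(orientation)
  stopifnot(amplitude >= 0, period > 0,
            warm_fraction > 0, warm_fraction < 1)
  structure(list(mean = mean, amplitude = amplitude, period = period,
                 warm_fraction = warm_fraction, orientation = orientation),
            class = "temp_pattern")
}

#' @export
print.temp_pattern <- function(x, ...) {
  cat(sprintf("<temp_pattern> %s, %g +/- %g degC, period %g h (warm %g%%)\n",
              x$orientation, x$mean, x$amplitude / 2, x$period,
              100 * x$warm_fraction))
  invisible(x)
}

# one segment row; pattern fields NA for constant segments
.segment_row <- function(start_h, end_h, pattern = NULL, value = NA_real_) {
  if (is.null(pattern)) {
    tibble::tibble(start_h = start_h, end_h = end_h, kind = "constant",
                   mean = NA_real_, amplitude = NA_real_, period = NA_real_,
                   warm_fraction = NA_real_, orientation = NA_character_,
                   value = value)
  } else {
    tibble::tibble(start_h = start_h, end_h = end_h, kind = "pattern",
                   mean = pattern$mean, amplitude = pattern$amplitude,
                   period = pattern$period,
                   warm_fraction = pattern$warm_fraction,
                   orientation = pattern$orientation, value = NA_real_)
  }
}

new_schedule <- function(segments, unit = NULL, unit_h = NA_real_) {
  pre_h <- if (nrow(segments)) max(segments$end_h) else 0
  if (nrow(segments)) {
    stopifnot(segments$start_h[1] == 0,
              all(segments$end_h > segments$start_h),
              all(abs(segments$start_h[-1] -
                      segments$end_h[-nrow(segments)]) < 1e-9))
  }
  if (is.null(unit) && !nrow(segments)) {
    stop("schedule needs at least one segment", call. = FALSE)
  }
  structure(list(segments = segments, unit = unit, unit_h = unit_h,
                 pre_h = pre_h),
            class = "temp_schedule")
}

#' Constant-temperature schedule
#'
#' @param value Temperature, degC.
#' @return A `temp_schedule`.
#' @export
constant_schedule <- function(value = 37) {
  new_schedule(.segment_row(0, 0)[0, ],
               unit = .segment_row(0, 24, value = value), unit_h = 24)
}

#' Single repeating pattern schedule
#'
#' @param pattern A [temp_pattern()]; the default is the nominal W12/C12
#'   37 +/- 1.5 degC cycle.
#' @return A `temp_schedule` repeating the pattern indefinitely.
#' @export
pattern_schedule <- function(pattern = temp_pattern()) {
  new_schedule(.segment_row(0, 0)[0, ],
               unit = .segment_row(0, pattern$period, pattern = pattern),
               unit_h = pattern$period)
}

#' Parse an alternating shift schedule specification
#'
#' An alternating shift schedule (ASS) "N-n1:n2" repeats every N days:
#' first n1/(n1+n2) of the unit under the reversed pattern, then the rest
#' under the normal pattern (R:N order). "28-5:2" therefore means 20 days
#' reversed then 8 days normal. The two patterns may be given different
#' amplitudes (e.g. to weaken only the reversed block).
#'
#' @param spec Character like `"7-5:2"`.
#' @param mean Cycle mean temperature, degC.
#' @param amplitude_normal,amplitude_reversed Peak-to-trough amplitudes of
#'   the normal and reversed blocks, degC.
#' @param first Which block opens each unit; the "(R:N)" shorthand puts
#'   the reversed block first.
#' @return A repeating `temp_schedule` whose unit is N days.
#' @export
#' @examples
#' parse_ass("7-5:2")    # 5 d reversed + 2 d normal
#' parse_ass("28-3:4")   # 12 d reversed + 16 d normal
parse_ass <- function(spec, mean = 37, amplitude_normal = 3,
                      amplitude_reversed = 3,
                      first = c("reversed", "normal")) {
  first <- match.arg(first)
  m <- regmatches(spec, regexec("^([0-9]+)-([0-9]+):([0-9]+)$", spec))[[1]]
  if (length(m) != 4) {
    stop("ASS spec must match \"N-n1:n2\", got: ", spec, call. = FALSE)
  }
  N <- as.integer(m[2]); n1 <- as.integer(m[3]); n2 <- as.integer(m[4])
  if (n1 < 1 || n2 < 1 || N < 2) {
    stop("ASS blocks must be at least one day each", call. = FALSE)
  }
  d1 <- N * n1 / (n1 + n2)
  if (abs(d1 - round(d1)) > 1e-9) {
    stop(sprintf("spec %s: %d days cannot be split %d:%d into whole days",
                 spec, N, n1, n2), call. = FALSE)
  }
  d1 <- round(d1)
  pat_r <- temp_pattern(mean = mean, amplitude = amplitude_reversed,
                        orientation = "reversed")
  pat_n <- temp_pattern(mean = mean, amplitude = amplitude_normal,
                        orientation = "normal")
  blocks <- if (first == "reversed") list(pat_r, pat_n) else list(pat_n, pat_r)
  lens <- if (first == "reversed") c(d1, N - d1) else c(N - d1, d1)
  unit <- dplyr::bind_rows(
    .segment_row(0, 24 * lens[1], pattern = blocks[[1]]),
    .segment_row(24 * lens[1], 24 * N, pattern = blocks[[2]])
  )
  new_schedule(.segment_row(0, 0)[0, ], unit = unit, unit_h = 24 * N)
}

#' Entrain-then-shift schedule
#'
#' The shift-work protocol: the normal pattern for `pre_days`, then the
#' alternating shift schedule `spec` indefinitely.
#'
#' @inheritParams parse_ass
#' @param pre_days Days of normal-pattern entrainment before the switch.
#' @return A `temp_schedule`.
#' @export
#' @examples
#' ass_schedule("7-5:2")                         # switch at day 50
#' ass_schedule("7-5:2", amplitude_reversed = 1) # weakened reversed block
ass_schedule <- function(spec, pre_days = 50, mean = 37,
                         amplitude_normal = 3, amplitude_reversed = 3,
                         first = c("reversed", "normal")) {
  ass <- parse_ass(spec, mean = mean, amplitude_normal = amplitude_normal,
                   amplitude_reversed = amplitude_reversed,
                   first = first)
  pre <- .segment_row(0, 24 * pre_days,
                      pattern = temp_pattern(mean = mean,
                                             amplitude = amplitude_normal))
  new_schedule(pre, unit = ass$unit, unit_h = ass$unit_h)
}

#' Rhythm on/off validation schedule
#'
#' Constant 37 degC before `rhythm_on_d`, the rhythmic pattern until
#' `rhythm_off_d`, and constant 37 degC afterwards -- the protocol used to
#' demonstrate synchronization onset and decay of a heterogeneous
#' population.
#'
#' @param orientation Orientation of the rhythmic segment.
#' @param rhythm_on_d,rhythm_off_d Days at which the rhythm starts and
#'   stops.
#' @param mean,amplitude Pattern mean and amplitude, degC.
#' @return A `temp_schedule`.
#' @export
validation_schedule <- function(orientation = c("normal", "reversed"),
                                rhythm_on_d = 10, rhythm_off_d = 65,
                                mean = 37, amplitude = 3) {
  orientation <- match.arg(orientation)
  segs <- dplyr::bind_rows(
    .segment_row(0, 24 * rhythm_on_d, value = mean),
    .segment_row(24 * rhythm_on_d, 24 * rhythm_off_d,
                 pattern = temp_pattern(mean = mean, amplitude = amplitude,
                                        orientation = orientation))
  )
  new_schedule(segs, unit = .segment_row(0, 24, value = mean), unit_h = 24)
}

# locate the active segment row for each time (vectorized)
.active_segment <- function(schedule, t) {
  seg_of <- function(ti) {
    if (ti < schedule$pre_h - 1e-9 && nrow(schedule$segments)) {
      i <- findInterval(ti + 1e-9, schedule$segments$start_h)
      schedule$segments[i, ]
    } else {
      if (is.null(schedule$unit)) {
        stop("time ", ti, " h is outside the schedule's domain",
             call. = FALSE)
      }
      tu <- (ti - schedule$pre_h) %% schedule$unit_h
      i <- findInterval(tu + 1e-9, schedule$unit$start_h)
      schedule$unit[i, ]
    }
  }
  dplyr::bind_rows(lapply(t, seg_of))
}

.pattern_value <- function(seg, t) {
  zt <- t %% seg$period
  half <- seg$period * seg$warm_fraction
  warm <- if (seg$orientation == "normal") {
    zt < half - 1e-9 | zt > seg$period - 1e-9
  } else {
    # reversed: cold opens the cycle; warm on the trailing warm_fraction
    zt >= seg$period * (1 - seg$warm_fraction) - 1e-9
  }
  ifelse(warm, seg$mean + seg$amplitude / 2, seg$mean - seg$amplitude / 2)
}

#' Evaluate a schedule
#'
#' Returns the square-wave temperature and the active pattern's cycle
#' average at each time. Intervals are left-closed/right-open, so the warm
#' value holds on ZT [0, 12) for the default normal pattern.
#'
#' @param schedule A `temp_schedule`.
#' @param t Times, h (>= 0).
#' @return A tibble with columns `time_h`, `temp_c` and `temp_mean_c`.
#' @export
#' @examples
#' temperature_at(pattern_schedule(), c(6, 18))   # 38.5, 35.5
temperature_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "temp_schedule"), all(t >= 0))
  segs <- .active_segment(schedule, t)
  temp <- numeric(length(t))
  tavg <- numeric(length(t))
  for (i in seq_along(t)) {
    seg <- segs[i, ]
    if (seg$kind == "constant") {
      temp[i] <- seg$value
      tavg[i] <- seg$value
    } else {
      temp[i] <- .pattern_value(seg, t[i])
      tavg[i] <- seg$mean + seg$amplitude * (seg$warm_fraction - 0.5)
    }
  }
  tibble::tibble(time_h = t, temp_c = temp, temp_mean_c = tavg)
}

# pattern edges of one segment row within (lo, hi]
.segment_edges <- function(seg, lo, hi) {
  lo <- max(lo, seg$start_h); hi <- min(hi, seg$end_h)
  if (hi <= lo) return(numeric(0))
  if (seg$kind == "constant") return(numeric(0))
  per <- seg$period
  offs <- if (seg$orientation == "normal") {
    c(0, per * seg$warm_fraction)
  } else {
    c(0, per * (1 - seg$warm_fraction))
  }
  edges <- unlist(lapply(offs, function(o) {
    k <- seq(floor((lo - o) / per), ceiling((hi - o) / per))
    o + k * per
  }))
  edges[edges > lo + 1e-9 & edges <= hi + 1e-9]
}

#' Schedule discontinuity times
#'
#' All warm/cold square-wave edges and segment boundaries in `(t0, t1]`,
#' sorted and deduplicated. The simulator restarts the integrator at each
#' of these times so the square wave is honored exactly.
#'
#' @param schedule A `temp_schedule`.
#' @param t_span Length-2 numeric `c(t0, t1)`, h.
#' @return Sorted numeric vector of switch times, h.
#' @export
#' @examples
#' discontinuities(pattern_schedule(), c(0, 48))  # 12 24 36 48
discontinuities <- function(schedule, t_span) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  lo <- t_span[1]; hi <- t_span[2]
  out <- numeric(0)
  segs <- schedule$segments
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      out <- c(out, .segment_edges(segs[i, ], lo, hi), segs$end_h[i])
    }
  }
  if (!is.null(schedule$unit) && hi > schedule$pre_h) {
    k_max <- ceiling((hi - schedule$pre_h) / schedule$unit_h)
    for (k in seq_len(k_max) - 1L) {
      base <- schedule$pre_h + k * schedule$unit_h
      for (i in seq_len(nrow(schedule$unit))) {
        seg <- schedule$unit[i, ]
        seg$start_h <- seg$start_h + base
        seg$end_h <- seg$end_h + base
        out <- c(out, .segment_edges(seg, lo, hi), seg$end_h)
      }
    }
  }
  out <- sort(unique(round(out[out > lo + 1e-9 & out <= hi + 1e-9], 9)))
  if (!length(out)) return(numeric(0))
  # keep only true temperature jumps: segment boundaries between equal
  # values (constant blocks, pattern inversions that preserve the current
  # level) are not discontinuities of the forcing
  before <- temperature_at(schedule, pmax(out - 1e-6, 0))$temp_c
  after <- temperature_at(schedule, out + 1e-6)$temp_c
  out[abs(after - before) > 1e-9]
}

#' @export
print.temp_schedule <- function(x, ...) {
  cat("<temp_schedule>\n")
  if (nrow(x$segments)) {
    cat(sprintf("  %d leading segment(s) over %g d, then repeating unit of %g d\n",
                nrow(x$segments), x$pre_h / 24, x$unit_h / 24))
  } else {
    cat(sprintf("  repeating unit of %g h\n", x$unit_h))
  }
  invisible(x)
}

#' @export
as_tibble.temp_schedule <- function(x, ...) {
  pre <- x$segments
  unit <- x$unit
  if (!is.null(unit)) {
    unit$start_h <- unit$start_h + x$pre_h
    unit$end_h <- unit$end_h + x$pre_h
    unit$repeating <- TRUE
  }
  if (nrow(pre)) pre$repeating <- FALSE
  dplyr::bind_rows(pre, unit)
}
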