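# In-silico experiments: rhythm on/off validation, amplitude and mean
# sweeps, the Arnold entrainment grid, alternating shift schedules, and the
# individualized-response sweep with its sensitivity regression.

.sweep_row <- function(ens, component, window, reference = 0,
                       period = 24) {
  g <- glance(sync_report(ens, component, window = window,
                          reference = reference, period = period))
  g$mean_level <- mean(.ens_component(ens, component)[,
    ens$time_h >= window[1] & ens$time_h <= window[2]])
  g
}

#' Amplitude sweep of the temperature zeitgeber
#'
#' Simulates one heterogeneous population under square-wave rhythms of
#' increasing peak-to-trough amplitude (including the rhythm-free constant
#' case at amplitude 0) and, optionally, the decoupled control in which
#' `khsf1 = 0` severs the cascade-to-clock coupling. Reports R_syn and
#' ensemble summaries for the cascade output (actHSF1) and the clock
#' marker (Per/Cry mRNA).
#'
#' @param amplitudes Peak-to-trough amplitudes, degC (0 = constant).
#' @param n_cells Population size.
#' @param mean Cycle mean temperature, degC.
#' @param include_decoupled Add the `khsf1 = 0` control (run under the
#'   nominal amplitude-3 rhythm; the clock cannot see it).
#' @param seed Sobol seed for the population.
#' @param burn_in Discarded transient, h.
#' @param window_h R_syn evaluation span after burn-in, h.
#' @param dt Output grid, h.
#' @param components Components summarised.
#' @return A tibble (one row per amplitude x component) with `amplitude`,
#'   `decoupled`, `component`, `r_syn`, ensemble phase/period and
#'   dispersion columns, and `mean_level`.
#' @export
run_amplitude_sweep <- function(amplitudes = c(0, 1, 3, 5), n_cells = 200,
                                mean = 37, include_decoupled = TRUE,
                                seed = 0, burn_in = 480, window_h = 1200,
                                dt = 0.25,
                                components = c("actHSF1", "PerCry_mRNA")) {
  stopifnot(all(amplitudes >= 0))
  pop <- sample_population(n_cells, seed = seed)
  t_end <- burn_in + window_h
  window <- c(burn_in, t_end)
  one <- function(cells, amp, decoupled) {
    sched <- if (amp > 0) {
      pattern_schedule(temp_pattern(mean = mean, amplitude = amp))
    } else {
      constant_schedule(mean)
    }
    ens <- simulate_population(cells, sched, t_end = t_end, dt = dt,
                               keep = components)
    purrr::map_dfr(components, function(cmp) {
      dplyr::bind_cols(
        tibble::tibble(amplitude = amp, decoupled = decoupled),
        .sweep_row(ens, cmp, window))
    })
  }
  out <- purrr::map_dfr(amplitudes, function(a) one(pop, a, FALSE))
  if (include_decoupled) {
    pop0 <- dplyr::mutate(pop, khsf1 = 0)
    out <- dplyr::bind_rows(out, one(pop0, 3, TRUE))
  }
  out
}

#' Mean-temperature sweep
#'
#' Varies the cycle average of the zeitgeber at fixed amplitude. Raising
#' the mean raises the tonic drive into the cascade (higher single-cell
#' actHSF1 levels) without materially changing clock synchronization --
#' the variation, not the magnitude, of temperature is what entrains.
#'
#' @param means Cycle means, degC.
#' @param amplitude Fixed peak-to-trough amplitude, degC.
#' @inheritParams run_amplitude_sweep
#' @return A tibble, one row per mean x component.
#' @export
run_mean_sweep <- function(means = c(32, 34, 37, 40), amplitude = 3,
                           n_cells = 200, seed = 0, burn_in = 480,
                           window_h = 1200, dt = 0.25,
                           components = c("actHSF1", "PerCry_mRNA")) {
  pop <- sample_population(n_cells, seed = seed)
  t_end <- burn_in + window_h
  purrr::map_dfr(means, function(mu) {
    ens <- simulate_population(
      pop, pattern_schedule(temp_pattern(mean = mu, amplitude = amplitude)),
      t_end = t_end, dt = dt, keep = components)
    purrr::map_dfr(components, function(cmp) {
      dplyr::bind_cols(tibble::tibble(mean = mu, amplitude = amplitude),
                       .sweep_row(ens, cmp, c(burn_in, t_end)))
    })
  })
}

#' Arnold entrainment grid
#'
#' Maps ensemble entrainment on the zeitgeber period x amplitude plane. A
#' grid point is called entrained when the realized ensemble period over
#' the last `eval_cycles` zeitgeber cycles is within `period_tol` of the
#' zeitgeber period. The entrainment phase is reported relative to the
#' cold-phase onset.
#'
#' @param periods Zeitgeber periods, h.
#' @param amplitudes Peak-to-trough amplitudes, degC.
#' @param n_cells Population size (smaller than the other experiments; the
#'   grid multiplies runs).
#' @param eval_cycles Trailing cycles used for the entrainment call.
#' @param period_tol Entrainment tolerance on the realized period, h.
#' @inheritParams run_amplitude_sweep
#' @return A tibble with `zeitgeber_period`, `amplitude`, `entrained`,
#'   `r_syn`, `realized_period_h`, `phase_vs_cold_h`.
#' @export
run_arnold_grid <- function(periods = c(21, 22, 23, 24, 25, 26, 27),
                            amplitudes = c(1, 3, 5), n_cells = 50,
                            mean = 37, seed = 0, burn_in = 480,
                            eval_cycles = 10, period_tol = 0.1,
                            dt = 0.25) {
  pop <- sample_population(n_cells, seed = seed)
  grid <- expand.grid(period = periods, amplitude = amplitudes)
  purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    P <- grid$period[k]; A <- grid$amplitude[k]
    t_end <- burn_in + 2 * eval_cycles * P
    ens <- simulate_population(
      pop, pattern_schedule(temp_pattern(mean = mean, amplitude = A,
                                         period = P)),
      t_end = t_end, dt = dt, keep = "PerCry_mRNA")
    window <- c(t_end - eval_cycles * P, t_end)
    avg <- ensemble_average(ens)
    sel <- avg$time_h >= window[1]
    per <- suppressWarnings(period_of(avg$value[sel], avg$time_h[sel]))
    ph <- suppressWarnings(
      phase_of(avg$value[sel], avg$time_h[sel], reference = P / 2,
               period = P, stability_tol = Inf))
    tibble::tibble(
      zeitgeber_period = P, amplitude = A,
      entrained = is.finite(per) && abs(per - P) < period_tol,
      r_syn = suppressWarnings(r_syn(ens, "PerCry_mRNA", window = window)),
      realized_period_h = per, phase_vs_cold_h = ph)
  })
}

#' Rhythm on/off validation run
#'
#' The synchronization/desynchronization protocol: constant 37 degC, then
#' the rhythmic pattern (normal and reversed variants), then constant
#' again. Tracks the sliding-window R_syn and reports the times for it to
#' cross 0.5 rising (after rhythm onset) and falling (after removal).
#'
#' @param orientations Pattern orientations to run.
#' @param rhythm_on_d,rhythm_off_d,t_end_d Protocol timeline, days.
#' @param window_h Sliding R_syn window, h.
#' @param step_h Window step, h.
#' @inheritParams run_amplitude_sweep
#' @return A `validation_result` with `$r_syn_trace` (tibble), `$summary`
#'   (per-orientation sync/desync times and entrained phase/period) and
#'   `$phase_period` (per-cell metrics in the entrained stretch).
#' @export
run_validation <- function(n_cells = 200,
                           orientations = c("normal", "reversed"),
                           rhythm_on_d = 10, rhythm_off_d = 65,
                           t_end_d = 110, amplitude = 3, seed = 0,
                           window_h = 720, step_h = 24, dt = 0.25) {
  pop <- sample_population(n_cells, seed = seed)
  res <- purrr::map(orientations, function(ori) {
    sched <- validation_schedule(ori, rhythm_on_d, rhythm_off_d,
                                 amplitude = amplitude)
    ens <- simulate_population(pop, sched, t_end = 24 * t_end_d, dt = dt,
                               keep = "PerCry_mRNA")
    trace <- r_syn_windowed(ens, "PerCry_mRNA", window_h = window_h,
                            step_h = step_h)
    trace$orientation <- ori
    # entrained-stage per-cell metrics (last 10 d of the rhythmic block)
    rep_win <- c(24 * (rhythm_off_d - 10), 24 * rhythm_off_d)
    sr <- sync_report(ens, "PerCry_mRNA", window = rep_win,
                      reference = zt_reference(ori, "warm"))
    pc <- sr$per_cell; pc$orientation <- ori
    # crossing times: window mid relative to the switch
    on_h <- 24 * rhythm_on_d; off_h <- 24 * rhythm_off_d
    rising <- trace$window_mid_h[trace$window_mid_h > on_h &
                                   trace$r_syn >= 0.5]
    falling <- trace$window_mid_h[trace$window_mid_h > off_h &
                                    trace$r_syn < 0.5]
    list(trace = trace, per_cell = pc, summary = tibble::tibble(
      orientation = ori,
      sync_time_d = if (length(rising)) (min(rising) - on_h) / 24
                    else NA_real_,
      desync_time_d = if (length(falling)) (min(falling) - off_h) / 24
                      else NA_real_,
      entrained_phase_h = sr$ensemble_phase_h,
      entrained_period_h = sr$ensemble_period_h,
      peak_r_syn = max(trace$r_syn, na.rm = TRUE)))
  })
  structure(list(
    r_syn_trace = purrr::map_dfr(res, "trace"),
    phase_period = purrr::map_dfr(res, "per_cell"),
    summary = purrr::map_dfr(res, "summary")),
    class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.validation_result <- function(x, ...) x$r_syn_trace

# per-cycle ensemble phase trace: every mean-field peak, tagged by day,
# phase relative to the normal pattern's warm onset (global ZT)
.phase_trace <- function(avg_value, time_h, period = 24) {
  pk <- find_peaks(avg_value, time_h)
  tibble::tibble(day = floor(pk$time / 24),
                 peak_time_h = pk$time,
                 phase_h = pk$time %% period)
}

#' Alternating shift schedule run
#'
#' Entrains a population to the normal pattern for `pre_days`, switches to
#' the alternating shift schedule, and tracks the per-cycle ensemble phase
#' and the 24 h-windowed R_syn through at least 100 post-switch days. The
#' long-run phase shift is the circular mean phase over the final
#' `summary_units` schedule units minus the pre-switch entrained phase,
#' wrapped to \[-12, 12) h so antiphase adoption reports -12 h (a phase
#' advance).
#'
#' @param spec ASS specification, e.g. `"7-5:2"` (R:N order).
#' @param pre_days Normal-pattern entrainment before the switch, days.
#' @param post_days Days simulated after the switch.
#' @param amplitude_normal,amplitude_reversed Block amplitudes, degC.
#' @param summary_units Trailing schedule units averaged for the long-run
#'   phase.
#' @inheritParams run_amplitude_sweep
#' @return An `ass_result` with `$phase_trace`, `$r_syn_trace` and a
#'   one-row `$summary`: pre/post phases, `phase_shift_h`,
#'   `mean_post_r_syn` (whole post-switch course, transient included) and
#'   `adapted_r_syn` (final `summary_units` units only -- the attained
#'   synchronization state).
#' @export
run_ass <- function(spec = "7-5:2", n_cells = 200, pre_days = 50,
                    post_days = 100, amplitude_normal = 3,
                    amplitude_reversed = 3, seed = 0, dt = 0.25,
                    window_h = 24, summary_units = 3) {
  pop <- sample_population(n_cells, seed = seed)
  sched <- ass_schedule(spec, pre_days = pre_days,
                        amplitude_normal = amplitude_normal,
                        amplitude_reversed = amplitude_reversed)
  t_end <- 24 * (pre_days + post_days)
  ens <- simulate_population(pop, sched, t_end = t_end, dt = dt,
                             keep = "PerCry_mRNA")
  avg <- ensemble_average(ens, "PerCry_mRNA")
  ptr <- .phase_trace(avg$value, avg$time_h)
  rtr <- r_syn_windowed(ens, "PerCry_mRNA", window_h = window_h)
  unit_d <- sched$unit_h / 24
  # final `summary_units` complete schedule units
  last_unit_end <- pre_days + floor(post_days / unit_d) * unit_d
  adapt_lo <- last_unit_end - summary_units * unit_d
  pre_sel <- ptr$day >= pre_days - 10 & ptr$day < pre_days
  post_sel <- ptr$day >= adapt_lo & ptr$day < last_unit_end
  pre_phase <- .circ_mean(ptr$phase_h[pre_sel])
  post_phase <- .circ_mean(ptr$phase_h[post_sel])
  post_rs <- rtr$r_syn[rtr$window_start_h >= 24 * pre_days]
  adapted_rs <- rtr$r_syn[rtr$window_start_h >= 24 * adapt_lo &
                            rtr$window_start_h < 24 * last_unit_end]
  structure(list(
    spec = spec, phase_trace = ptr, r_syn_trace = rtr,
    ensemble_average = avg,
    summary = tibble::tibble(
      spec = spec,
      amplitude_normal = amplitude_normal,
      amplitude_reversed = amplitude_reversed,
      pre_phase_h = pre_phase, post_phase_h = post_phase,
      phase_shift_h = phase_shift(post_phase - pre_phase),
      mean_post_r_syn = mean(post_rs, na.rm = TRUE),
      adapted_r_syn = mean(adapted_rs, na.rm = TRUE))),
    class = "ass_result")
}

#' @export
print.ass_result <- function(x, ...) {
  cat(sprintf("<ass_result> %s\n", x$spec))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ass_result <- function(x, ...) x$r_syn_trace

#' @export
glance.ass_result <- function(x, ...) x$summary

#' Individualized-response sweep
#'
#' Samples subjects differing in their thermosensing triple (vact0_ts1,
#' vact1_ts1, kb_ts2), builds a heterogeneous cell population around each
#' subject, and measures the subject's mean 24 h-windowed Per/Cry mRNA
#' R_syn over the post-switch course under the nominal schedule and each
#' alternating shift schedule. The same population (per subject) is reused
#' across schedules so schedules are compared like-for-like.
#'
#' @param n_subjects Number of subjects.
#' @param cells_per_subject Cells per subject population.
#' @param schedules Character vector: `"nominal"` and/or ASS specs.
#' @param pre_days,post_days Horizon around the schedule switch, days.
#' @param range_frac Within-subject cell heterogeneity (fraction of the
#'   subject's parameter values); `NULL` for the calibrated default of
#'   [sample_population()].
#' @inheritParams run_amplitude_sweep
#' @return A tibble: `subject`, the sensing triple, `schedule`,
#'   `mean_r_syn`.
#' @export
run_individual_sweep <- function(n_subjects = 50, cells_per_subject = 100,
                                 schedules = c("nominal", "7-6:1",
                                               "7-5:2", "7-3:4"),
                                 pre_days = 15, post_days = 35,
                                 range_frac = NULL, seed = 0, dt = 0.25) {
  subjects <- sample_individuals(n_subjects, seed = seed)
  t_end <- 24 * (pre_days + post_days)
  post_from <- 24 * pre_days
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    base <- clock_params(vact0_ts1 = subjects$vact0_ts1[i],
                         vact1_ts1 = subjects$vact1_ts1[i],
                         kb_ts2 = subjects$kb_ts2[i])
    pop <- sample_population(cells_per_subject, nominal = base,
                             range_frac = range_frac, seed = seed + i)
    purrr::map_dfr(schedules, function(sp) {
      sched <- if (identical(sp, "nominal")) {
        pattern_schedule()
      } else {
        ass_schedule(sp, pre_days = pre_days)
      }
      ens <- simulate_population(pop, sched, t_end = t_end, dt = dt,
                                 keep = "PerCry_mRNA")
      rtr <- r_syn_windowed(ens, "PerCry_mRNA", window_h = 24,
                            from = post_from)
      tibble::tibble(subject = i,
                     vact0_ts1 = subjects$vact0_ts1[i],
                     vact1_ts1 = subjects$vact1_ts1[i],
                     kb_ts2 = subjects$kb_ts2[i],
                     schedule = sp,
                     mean_r_syn = mean(rtr$r_syn, na.rm = TRUE))
    })
  })
}

#' Sensitivity regression of synchronization on sensing parameters
#'
#' Ordinary least squares of a subject-level mean R_syn on the
#' thermosensing triple, `mean_r_syn ~ vact0_ts1 + vact1_ts1 + kb_ts2`,
#' fitted per schedule. p-values are the standard OLS t-tests, uncorrected.
#'
#' @param data Tibble from [run_individual_sweep()] (or any table with the
#'   triple and a `mean_r_syn` column).
#' @param schedule Optional schedule label to filter on (required when
#'   `data` holds several schedules).
#' @return A `sync_regression` wrapping the `lm` fit; [tidy()] gives
#'   coefficient estimates and p-values, [glance()] the fit summary.
#' @export
#' @examples
#' d <- tibble::tibble(vact0_ts1 = runif(20), vact1_ts1 = runif(20),
#'                     kb_ts2 = runif(20))
#' d$mean_r_syn <- 0.9 - 0.8 * d$vact0_ts1 + 0.1 * d$vact1_ts1
#' tidy(fit_sensitivity_regression(d))
fit_sensitivity_regression <- function(data, schedule = NULL) {
  if (!is.null(schedule)) {
    data <- data[data$schedule == schedule, , drop = FALSE]
  } else if ("schedule" %in% names(data) &&
             length(unique(data$schedule)) > 1) {
    stop("data holds several schedules; pass `schedule = `", call. = FALSE)
  }
  need <- c("vact0_ts1", "vact1_ts1", "kb_ts2", "mean_r_syn")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(mean_r_syn ~ vact0_ts1 + vact1_ts1 + kb_ts2,
                   data = data)
  if (fit$rank < 4) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(list(fit = fit, schedule = schedule, n = nrow(data)),
            class = "sync_regression")
}

#' @export
print.sync_regression <- function(x, ...) {
  cat(sprintf("<sync_regression>%s, n = %d subjects\n",
              if (is.null(x$schedule)) "" else paste0(" ", x$schedule),
              x$n))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.sync_regression <- function(x, ...) {
  cf <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p.value = unname(cf[, 4]))
}

#' @export
glance.sync_regression <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    schedule = if (is.null(x$schedule)) NA_character_ else x$schedule,
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    nobs = x$n)
}

#' Regression table across schedules
#'
#' Fits the sensitivity regression for every schedule present in an
#' individual-sweep table and stacks the coefficients, mirroring a
#' coefficient x schedule layout.
#'
#' @param data Tibble from [run_individual_sweep()].
#' @return A tibble: `schedule`, `term`, `estimate`, `p.value`.
#' @export
regression_table <- function(data) {
  purrr::map_dfr(unique(data$schedule), function(sp) {
    td <- tidy(fit_sensitivity_regression(data, schedule = sp))
    tibble::tibble(schedule = sp, term = td$term,
                   estimate = td$estimate, p.value = td$p.value)
  })
}
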