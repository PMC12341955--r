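test_that("noiseless linear data is recovered exactly by the regression", {
  set.seed(1)
  d <- tibble::tibble(vact0_ts1 = runif(30, 0.05, 0.3),
                      vact1_ts1 = runif(30, 0.3, 1.3),
                      kb_ts2 = runif(30, 10, 40))
  d$mean_r_syn <- 0.9 - 0.8 * d$vact0_ts1 + 0.1 * d$vact1_ts1 +
    0 * d$kb_ts2
  fit <- fit_sensitivity_regression(d)
  # lm warns that a noiseless fit is "essentially perfect" -- that is the
  # point of this check
  est <- suppressWarnings(tidy(fit)$estimate)
  expect_equal(est, c(0.9, -0.8, 0.1, 0), tolerance = 1e-10)
  # OLS is invariant to the subject ordering
  fit2 <- fit_sensitivity_regression(d[sample(30), ])
  expect_equal(suppressWarnings(tidy(fit2)$estimate), est,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit)$nobs), 30)
})

test_that("rank-deficient designs are refused", {
  d <- tibble::tibble(vact0_ts1 = rep(0.13, 10),
                      vact1_ts1 = rep(0.65, 10),
                      kb_ts2 = rep(20, 10),
                      mean_r_syn = runif(10))
  expect_error(fit_sensitivity_regression(d), "rank deficient")
})

test_that("regression tables stack one fit per schedule", {
  set.seed(2)
  d <- purrr::map_dfr(c("nominal", "7-5:2"), function(sp) {
    tibble::tibble(schedule = sp, vact0_ts1 = runif(12),
                   vact1_ts1 = runif(12), kb_ts2 = runif(12),
                   mean_r_syn = runif(12))
  })
  expect_error(fit_sensitivity_regression(d), "several schedules")
  tab <- regression_table(d)
  expect_equal(nrow(tab), 8)  # 4 coefficients x 2 schedules
  expect_named(tab, c("schedule", "term", "estimate", "p.value"))
})

test_that("a zero-detuning grid point entrains", {
  g <- run_arnold_grid(periods = 24, amplitudes = 3, n_cells = 6,
                       seed = 3, burn_in = 360, eval_cycles = 5)
  expect_true(g$entrained)
  expect_equal(g$realized_period_h, 24, tolerance = 0.05)
  expect_gt(g$r_syn, 0.3)
})

test_that("amplitude sweep output is tidy and rhythm beats no rhythm", {
  sw <- run_amplitude_sweep(amplitudes = c(0, 3), n_cells = 10,
                            include_decoupled = TRUE, seed = 4,
                            burn_in = 360, window_h = 600, dt = 0.5)
  expect_equal(nrow(sw), 6)  # (2 amplitudes + decoupled) x 2 components
  r3 <- sw$r_syn[sw$amplitude == 3 & !sw$decoupled &
                   sw$component == "PerCry_mRNA"]
  r0 <- sw$r_syn[sw$amplitude == 0 & sw$component == "PerCry_mRNA"]
  expect_gt(r3, r0)
  expect_gt(sw$r_syn[sw$amplitude == 3 & !sw$decoupled &
                       sw$component == "actHSF1"], 0.9)
})

test_that("rhythm onset synchronizes a population and removal relaxes it", {
  v <- run_validation(n_cells = 24, orientations = "reversed",
                      rhythm_on_d = 5, rhythm_off_d = 40, t_end_d = 70,
                      seed = 5, window_h = 240, step_h = 24, dt = 0.5)
  tr <- v$r_syn_trace
  during <- tr$r_syn[tr$window_mid_h > 24 * 25 & tr$window_mid_h < 24 * 40]
  after <- tr$r_syn[tr$window_start_h > 24 * 55]
  expect_gt(max(during), 0.8)
  expect_lt(min(after), min(0.5, max(during)))
  s <- v$summary
  expect_equal(s$entrained_period_h, 24, tolerance = 0.05)
  # synchronization is quicker than desynchronization
  desync <- ifelse(is.na(s$desync_time_d), 70 - 40, s$desync_time_d)
  expect_lt(s$sync_time_d, desync)
})

test_that("a short shift-schedule run is reproducible and well-formed", {
  r1 <- run_ass("7-5:2", n_cells = 8, pre_days = 10, post_days = 14,
                seed = 6, dt = 0.5)
  r2 <- run_ass("7-5:2", n_cells = 8, pre_days = 10, post_days = 14,
                seed = 6, dt = 0.5)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$r_syn_trace, r2$r_syn_trace)
  expect_true(all(c("pre_phase_h", "post_phase_h", "phase_shift_h",
                    "mean_post_r_syn", "adapted_r_syn") %in%
                    names(r1$summary)))
  expect_gte(r1$summary$phase_shift_h, -12)
  expect_lt(r1$summary$phase_shift_h, 12)
})

test_that("individual sweep rows are deterministic and one per schedule", {
  sw <- run_individual_sweep(n_subjects = 2, cells_per_subject = 4,
                             schedules = c("nominal", "7-5:2"),
                             pre_days = 6, post_days = 8, seed = 7,
                             dt = 0.5)
  expect_equal(nrow(sw), 4)
  expect_identical(
    sw,
    run_individual_sweep(n_subjects = 2, cells_per_subject = 4,
                         schedules = c("nominal", "7-5:2"),
                         pre_days = 6, post_days = 8, seed = 7, dt = 0.5))
  expect_true(all(is.finite(sw$mean_r_syn)))
})

test_that("raising the zeitgeber mean raises cascade output, not clock synchrony", {
  sw <- run_mean_sweep(means = c(33, 40), n_cells = 8, seed = 8,
                       burn_in = 360, window_h = 480, dt = 0.5)
  hsf <- sw[sw$component == "actHSF1", ]
  expect_gt(hsf$mean_level[hsf$mean == 40], hsf$mean_level[hsf$mean == 33])
  pc <- sw[sw$component == "PerCry_mRNA", ]
  expect_lt(abs(diff(pc$r_syn)), 0.35)  # far smaller than the amplitude effect
})
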