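test_that("peaks of a sinusoid are located to sub-grid accuracy", {
  t <- seq(0, 96, by = 0.1)
  pk <- find_peaks(sin(2 * pi * t / 24), t)
  expect_equal(pk$time, c(6, 30, 54, 78), tolerance = 1e-4)
  expect_true(attr(pk, "oscillatory"))
})

test_that("flat series are flagged non-oscillatory", {
  t <- seq(0, 96, by = 0.1)
  pk <- find_peaks(rep(2, length(t)), t)
  expect_equal(nrow(pk), 0)
  expect_false(attr(pk, "oscillatory"))
  expect_warning(p <- period_of(rep(2, length(t)), t), "non-oscillatory")
  expect_true(is.na(p))
})

test_that("small ripple below the prominence threshold is rejected", {
  t <- seq(0, 96, by = 0.1)
  v <- sin(2 * pi * t / 24) + 0.01 * sin(2 * pi * t / 3)
  pk <- find_peaks(v, t)
  expect_equal(nrow(pk), 4)  # one peak per 24 h cycle
  expect_equal(pk$time, c(6, 30, 54, 78), tolerance = 0.2)
})

test_that("period estimation averages steady-stage peak spacings", {
  t <- seq(0, 480, by = 0.1)
  expect_equal(period_of(sin(2 * pi * t / 24), t), 24, tolerance = 1e-3)
  expect_equal(period_of(cos(2 * pi * t / 23.8), t), 23.8,
               tolerance = 1e-3)
})

test_that("phase measurement respects the reference onset", {
  t <- seq(0, 240, by = 0.1)
  v <- sin(2 * pi * (t - 5) / 24)
  expect_equal(phase_of(v, t), 11, tolerance = 1e-3)  # peak at ZT 11
  expect_equal(phase_of(v, t, reference = zt_reference("reversed")),
               23, tolerance = 1e-3)                  # 12 h translate
  expect_equal(zt_reference("normal", "cold"), 12)
  expect_equal(zt_reference("reversed", "warm"), 12)
  # a drifting (unentrained) oscillation is flagged
  expect_warning(
    ph <- phase_of(sin(2 * pi * t / 21), t, stability_tol = 0.1),
    "unentrained")
  expect_true(is.na(ph))
})

test_that("phase differences wrap to [-12, 12)", {
  expect_equal(phase_shift(17 - 5), -12)
  expect_equal(phase_shift(c(-13, 13, 5, -5)), c(11, -11, 5, -5))
})

test_that("R_syn matches a direct evaluation on a 3-cell toy", {
  t <- seq(0, 72, by = 0.5)
  m <- rbind(1.0 + 0.9 * sin(2 * pi * t / 24),
             0.8 + 1.1 * sin(2 * pi * (t - 2) / 24),
             1.2 + 0.7 * sin(2 * pi * (t + 3) / 24))
  # spreadsheet-style evaluation: time averages with the 1/T convention
  tavg <- function(x) sum(x) / length(x)
  mf <- colMeans(m)
  num <- tavg(mf^2) - tavg(mf)^2
  den <- mean(apply(m, 1, function(x) tavg(x^2) - tavg(x)^2))
  expect_equal(r_syn(m, time = t), num / den, tolerance = 1e-12)
  expect_true(r_syn(m, time = t) >= 0 && r_syn(m, time = t) <= 1)
})

test_that("R_syn limits: identical cells 1, uniform phases near 0", {
  t <- seq(0, 120, by = 0.25)
  base <- 2 + sin(2 * pi * t / 24)
  ident <- matrix(rep(base, 4), nrow = 4, byrow = TRUE)
  expect_equal(r_syn(ident, time = t), 1, tolerance = 1e-12)
  phases <- (seq_len(1000) - 1) / 1000 * 24
  disp <- t(vapply(phases, function(p) sin(2 * pi * (t - p) / 24),
                   numeric(length(t))))
  expect_lt(r_syn(disp, time = t), 0.01)
})

test_that("R_syn is invariant to a common affine rescaling", {
  t <- seq(0, 96, by = 0.5)
  m <- rbind(sin(2 * pi * t / 24), sin(2 * pi * (t - 4) / 24),
             sin(2 * pi * (t - 9) / 24))
  expect_equal(r_syn(3.7 * m + 11, time = t), r_syn(m, time = t),
               tolerance = 1e-12)
})

test_that("degenerate R_syn is flagged, not silently zero or one", {
  m <- matrix(5, nrow = 3, ncol = 10)
  expect_warning(v <- r_syn(m, time = 1:10), "undefined")
  expect_true(is.na(v))
  expect_error(r_syn(m[1, , drop = FALSE], time = 1:10), "2 cells")
})

test_that("windowed R_syn tiles the requested span", {
  t <- seq(0, 96, by = 0.5)
  m <- rbind(sin(2 * pi * t / 24), sin(2 * pi * (t - 1) / 24))
  w <- r_syn_windowed(m, window_h = 24, time = t)
  expect_equal(w$window_start_h, c(0, 24, 48, 72))
  expect_true(all(w$r_syn > 0.9))
})

test_that("sync_report summarises an entrained ensemble sensibly", {
  ens <- small_rhythmic_ensemble()
  rep <- sync_report(ens, "PerCry_mRNA", burn_in = 480)
  g <- glance(rep)
  expect_equal(g$ensemble_period_h, 24, tolerance = 0.05)
  expect_gt(g$r_syn, 0.5)
  pc <- tidy(rep)
  expect_equal(nrow(pc), 12)
  expect_true(all(is.finite(pc$period_h)))
  expect_true(all(pc$phase_h >= 0 & pc$phase_h < 24, na.rm = TRUE))
})
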