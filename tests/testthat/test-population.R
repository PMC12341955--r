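test_that("zero-width ranges return exact copies of the nominal set", {
  pop <- sample_population(5, range_frac = 0, seed = 1)
  nom <- default_params()
  for (nm in param_names()) {
    expect_true(all(pop[[nm]] == nom[[nm]]), info = nm)
  }
})

test_that("sampled parameters honor their ranges and centring", {
  pop <- sample_population(1024, range_frac = 0.1, seed = 0,
                           vary = c("v1b", "kb_ts2", "k1d"))
  for (nm in c("v1b", "kb_ts2", "k1d")) {
    nomv <- default_params()[[nm]]
    expect_gte(min(pop[[nm]]), 0.9 * nomv)
    expect_lte(max(pop[[nm]]), 1.1 * nomv)
    expect_lt(abs(mean(pop[[nm]]) / nomv - 1), 0.005)
  }
  # untouched parameters stay nominal
  expect_true(all(pop$khsf1 == 39.97))
  # determinism contract
  expect_identical(sample_population(64, seed = 9),
                   sample_population(64, seed = 9))
})

test_that("default heterogeneity varies cascade wider than clock", {
  pop <- sample_population(256, seed = 2)
  spread <- function(nm) diff(range(pop[[nm]])) / default_params()[[nm]]
  expect_gt(spread("vb_ts2"), 0.15)   # cascade ~ +/-10%
  expect_lt(spread("v1b"), 0.05)      # clock ~ +/-2%
  expect_true(all(pop$n == 3) && all(pop$khsf1_ci == 1))
})

test_that("individual sensing triples are log-uniform within [0.5x, 2x]", {
  ind <- sample_individuals(128, seed = 5)
  expect_named(ind, c("subject", "vact0_ts1", "vact1_ts1", "kb_ts2"))
  expect_gte(min(ind$vact0_ts1), 0.5 * 0.13)
  expect_lte(max(ind$vact0_ts1), 2 * 0.13)
  # log-uniform: median of log-ratios near 0
  expect_lt(abs(median(log(ind$kb_ts2 / 20))), 0.1)
  expect_identical(ind, sample_individuals(128, seed = 5))
})

test_that("identical cells yield identical trajectories and their own mean", {
  cells <- sample_population(3, range_frac = 0, seed = 0)
  ens <- simulate_population(cells, pattern_schedule(), t_end = 240,
                             dt = 0.5, keep = "PerCry_mRNA")
  m <- ens$components$PerCry_mRNA
  expect_equal(m[1, ], m[2, ], tolerance = 1e-12)
  expect_equal(ensemble_average(ens)$value, m[3, ], tolerance = 1e-12)
})

test_that("cells are uncoupled: removing one leaves the others unchanged", {
  cells <- sample_population(3, seed = 21)
  full <- simulate_population(cells, pattern_schedule(), t_end = 240,
                              dt = 0.5, keep = "PerCry_mRNA",
                              rtol = 1e-10, atol = 1e-12)
  two <- simulate_population(cells[1:2, ], pattern_schedule(),
                             t_end = 240, dt = 0.5, keep = "PerCry_mRNA",
                             rtol = 1e-10, atol = 1e-12)
  expect_equal(full$components$PerCry_mRNA[1:2, ],
               two$components$PerCry_mRNA, tolerance = 1e-5)
})

test_that("stacked-population and single-cell integrations agree", {
  cells <- sample_population(2, seed = 13)
  ens <- simulate_population(cells, pattern_schedule(), t_end = 240,
                             dt = 0.5, rtol = 1e-10, atol = 1e-12)
  solo <- simulate_cell(cells[2, ], pattern_schedule(), t_end = 240,
                        dt = 0.5, rtol = 1e-10, atol = 1e-12)
  for (cmp in c("TS2", "actHSF1", "PerCry_mRNA", "CLOCKBMAL1")) {
    expect_equal(ens$components[[cmp]][2, ], solo[[cmp]],
                 tolerance = 1e-6, ignore_attr = TRUE, info = cmp)
  }
})

test_that("ensemble averaging is the pointwise mean field", {
  fake <- structure(list(
    time_h = 0:3,
    components = list(x = rbind(rep(1, 4), rep(2, 4), rep(3, 4))),
    cells = NULL, schedule = NULL, dt = 1), class = "clock_ensemble")
  expect_equal(ensemble_average(fake, "x")$value, rep(2, 4))
  t <- seq(0, 24, 0.5)
  anti <- structure(list(
    time_h = t,
    components = list(x = rbind(sin(2 * pi * t / 24),
                                -sin(2 * pi * t / 24))),
    cells = NULL, schedule = NULL, dt = 0.5), class = "clock_ensemble")
  expect_equal(ensemble_average(anti, "x")$value, rep(0, length(t)),
               tolerance = 1e-12)
  expect_error(ensemble_average(fake, "nope"), "not stored")
})

test_that("tidy() unrolls an ensemble to long form", {
  ens <- small_rhythmic_ensemble()
  long <- tidy(ens)
  expect_named(long, c("component", "cell", "time_h", "value"))
  expect_equal(nrow(long), 2 * 12 * length(ens$time_h))
})
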