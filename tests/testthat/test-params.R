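test_that("nominal defaults reproduce the published parameter table", {
  p <- default_params()
  expect_length(p, 41)
  expect_equal(p$vact0_ts1, 0.13)
  expect_equal(p$HSF1tot, 20.89)
  expect_equal(p$khsf1, 39.97)
  expect_equal(p$v1b, 9)
  expect_equal(p$k4d, 0.75)
  expect_equal(p$kT, 27.17)
  expect_equal(p$khsf1_ci, 1)
  # all rates/capacities non-negative, Hill exponents >= 1
  expect_true(all(unlist(p) >= 0))
  expect_true(all(unlist(p[c("n", "p", "q", "r")]) >= 1))
})

test_that("parameter construction validates overrides", {
  p <- clock_params(khsf1 = 0)
  expect_equal(p$khsf1, 0)
  expect_equal(p$v1b, 9)  # untouched
  expect_error(clock_params(nosuch = 1), "unknown parameter")
  expect_error(clock_params(vd_ts2 = -1), "vd_ts2")
  expect_error(clock_params(p = 0.5), "Hill")
  expect_error(clock_params(1), "named")
})

test_that("parameter tables round-trip through the canonical vector form", {
  pv <- thermoclock:::as_param_vector(default_params())
  expect_named(pv, param_names())
  expect_error(thermoclock:::as_param_vector(c(v1b = 9)), "missing")
})
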