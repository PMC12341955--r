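test_that("square-wave evaluation follows the printed branch convention", {
  sch <- pattern_schedule()  # normal, 37 +/- 1.5
  expect_equal(temperature_at(sch, c(0, 6, 11.99))$temp_c,
               rep(38.5, 3))
  expect_equal(temperature_at(sch, c(12, 18, 23.99))$temp_c,
               rep(35.5, 3))
  rev <- pattern_schedule(temp_pattern(orientation = "reversed"))
  expect_equal(temperature_at(rev, 6)$temp_c, 35.5)
  expect_equal(temperature_at(rev, 18)$temp_c, 38.5)
  expect_equal(temperature_at(sch, 6)$temp_mean_c, 37)
})

test_that("reversed pattern is the 12 h translate of the normal pattern", {
  tn <- pattern_schedule(temp_pattern())
  tr <- pattern_schedule(temp_pattern(orientation = "reversed"))
  t <- seq(0, 47.5, by = 0.5)
  expect_equal(temperature_at(tr, t)$temp_c,
               temperature_at(tn, t + 12)$temp_c)
})

test_that("cycle time-average equals the declared mean", {
  for (pat in list(temp_pattern(), temp_pattern(amplitude = 5),
                   temp_pattern(orientation = "reversed"))) {
    sch <- pattern_schedule(pat)
    t <- seq(0, 24 - 0.01, by = 0.01)
    expect_equal(mean(temperature_at(sch, t)$temp_c), 37, tolerance = 1e-9)
  }
})

test_that("ASS grammar parses and scales block lengths", {
  s1 <- parse_ass("7-5:2")
  expect_equal(s1$unit_h, 7 * 24)
  expect_equal(s1$unit$end_h[1], 5 * 24)           # 5 d reversed first
  expect_equal(s1$unit$orientation, c("reversed", "normal"))
  s2 <- parse_ass("28-5:2")                         # 20:8 split
  expect_equal(s2$unit$end_h[1], 20 * 24)
  s3 <- parse_ass("28-3:4")                         # 12:16 split
  expect_equal(s3$unit$end_h[1], 12 * 24)
  expect_error(parse_ass("7-2:3"), "whole days")
  expect_error(parse_ass("7-5-2"), "N-n1:n2")
  expect_error(parse_ass("2-0:2"), "at least one day")
  # normal-first variant flips the block order
  s4 <- parse_ass("7-5:2", first = "normal")
  expect_equal(s4$unit$orientation, c("normal", "reversed"))
  expect_equal(s4$unit$end_h[1], 2 * 24)
})

test_that("ASS evaluation is periodic with the unit period", {
  sch <- parse_ass("7-5:2")
  t <- seq(0, 7 * 24 - 0.5, by = 3.5)
  expect_equal(temperature_at(sch, t)$temp_c,
               temperature_at(sch, t + 7 * 24)$temp_c)
  # reversed block opens the unit: cold at ZT 0-12 on day 0
  expect_equal(temperature_at(sch, 6)$temp_c, 35.5)
  # normal block on day 5
  expect_equal(temperature_at(sch, 5 * 24 + 6)$temp_c, 38.5)
})

test_that("discontinuities enumerate exactly the temperature jumps", {
  expect_identical(discontinuities(constant_schedule(37), c(0, 96)),
                   numeric(0))
  expect_equal(discontinuities(pattern_schedule(), c(0, 48)),
               c(12, 24, 36, 48))
  # 7-5:2 unit: 12 h edges, except the pattern inversions merge two
  # same-level half-cycles into a 24 h stretch (no jump at day 5 ZT0 or at
  # the unit boundary)
  d <- discontinuities(parse_ass("7-5:2"), c(0, 7 * 24))
  expect_equal(d, setdiff(seq(12, 168, by = 12), c(120, 168)))
  # entrain-then-shift: at day 50 the normal pattern's trailing cold
  # half-cycle runs straight into the reversed pattern's leading cold
  # half-cycle, so the first post-switch jump is at day 50 ZT12
  d2 <- discontinuities(ass_schedule("7-5:2", pre_days = 50),
                        c(49 * 24, 52 * 24))
  expect_equal(d2, c(1188, 1212, 1224, 1236, 1248))
})

test_that("schedules refuse evaluation outside their domain", {
  sch <- validation_schedule()
  expect_error(temperature_at(sch, -1))
  expect_equal(temperature_at(sch, c(5 * 24, 20 * 24, 70 * 24))$temp_c,
               c(37, 38.5, 37))
})
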