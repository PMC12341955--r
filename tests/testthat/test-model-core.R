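test_that("cascade derivatives vanish at the closed-form fixed point", {
  st <- default_init()
  st["TS1"] <- 7.4  # vact0_ts1 * 37 / vina_ts1
  d <- cascade_rhs(st, temp = 37, temp_mean = 37)
  expect_equal(unname(d["TS1"]), 0, tolerance = 1e-12)
  # the deviation term contributes exactly zero whenever T == Tavg
  d2 <- cascade_rhs(st, temp = 39, temp_mean = 39)
  expect_equal(unname(d2["TS1"]),
               0.13 * 39 + 0.65 * 0 - 0.65 * 7.4, tolerance = 1e-12)
  # TS2 fixed point from its own balance at TS1 = 7.4
  ts2_star <- (8 / 0.45) * 7.4^3 / (20^3 + 7.4^3)
  st["TS2"] <- ts2_star
  expect_equal(unname(cascade_rhs(st, 37, 37)["TS2"]), 0,
               tolerance = 1e-12)
  fp <- cascade_fixed_point()
  expect_equal(unname(fp["TS1"]), 7.4)
  expect_equal(unname(fp["TS2"]), ts2_star, tolerance = 1e-10)
  # no production, no steady TS signal
  fp0 <- cascade_fixed_point(clock_params(vact0_ts1 = 0), 37)
  expect_equal(unname(fp0[c("TS1", "TS2")]), c(0, 0))
})

test_that("the fixed-point oracle solves the HSF1/HSP balance", {
  fp <- cascade_fixed_point()
  st <- default_init()
  st[c("TS1", "TS2", "actHSF1", "indHSP")] <- fp
  d <- cascade_rhs(st, 37, 37)
  expect_equal(max(abs(d)), 0, tolerance = 1e-10)
  expect_lt(fp["actHSF1"], 20.89)  # bounded by the total pool
})

test_that("Hill terms are half-maximal at their Michaelis constants", {
  st <- default_init()
  st["nucPERCRY"] <- 2.16  # k4b
  d <- clock_rhs(st)
  production <- d["Bmal1_mRNA"] + 0.75 * st["Bmal1_mRNA"]
  expect_equal(unname(production), 3.6 / 2, tolerance = 1e-12)
})

test_that("derivative domain errors are raised, not clipped", {
  st <- default_init()
  st["indHSP"] <- 0
  expect_error(cascade_rhs(st, 37, 37), "indHSP")
  st <- default_init()
  st["CLOCKBMAL1"] <- 0
  expect_error(clock_rhs(st), "CLOCKBMAL1")
})

test_that("compiled and plain-R right-hand sides integrate identically", {
  # independent route: deSolve on the exported R derivatives, piecewise
  sched <- pattern_schedule()
  pv <- thermoclock:::as_param_vector(default_params())
  y <- default_init()
  out <- NULL
  for (a in seq(0, 60, by = 12)) {
    tw <- temperature_at(sched, a + 1e-6)
    o <- deSolve::ode(y, seq(a, a + 12, 0.5), model_rhs, pv,
                      temp = tw$temp_c, temp_mean = tw$temp_mean_c,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
    y <- o[nrow(o), -1]
    out <- rbind(out, o[-1, , drop = FALSE])
  }
  traj <- simulate_cell(t_end = 72, dt = 0.5)
  ours <- as.matrix(traj[traj$time_h > 0, -1])
  expect_lt(max(abs(ours - out[, -1])), 1e-5)
})

test_that("long constant-temperature integration reaches the algebraic fixed point", {
  traj <- simulate_cell(schedule = constant_schedule(37), t_end = 700,
                        dt = 0.5)
  fp <- cascade_fixed_point()
  last <- traj[nrow(traj), ]
  expect_equal(last$TS1, unname(fp["TS1"]), tolerance = 1e-6)
  expect_equal(last$TS2, unname(fp["TS2"]), tolerance = 1e-6)
})

test_that("positivity and the HSF1 pool bound hold along perturbed trajectories", {
  pop <- sample_population(5, seed = 42)
  ens <- simulate_population(pop, pattern_schedule(), t_end = 1200,
                             dt = 0.5)
  for (cmp in state_names()) {
    expect_true(all(ens$components[[cmp]] > 0), info = cmp)
  }
  expect_true(all(sweep(ens$components$actHSF1, 1, pop$HSF1tot, `<=`)))
  # explicit non-positive initial state is refused
  bad <- default_init(); bad["indHSP"] <- -1
  expect_error(simulate_cell(init = bad, t_end = 24))
})

test_that("khsf1 = 0 decouples the clock from the cascade", {
  p0 <- clock_params(khsf1 = 0)
  # cascade alive vs cascade production silenced: the clock cannot tell
  dead <- clock_params(khsf1 = 0, vact0_ts1 = 0, vact1_ts1 = 0)
  a <- simulate_cell(p0, pattern_schedule(), t_end = 480, dt = 0.5)
  b <- simulate_cell(dead, pattern_schedule(), t_end = 480, dt = 0.5)
  clock_cols <- setdiff(state_names(), c("TS1", "TS2", "actHSF1",
                                         "indHSP"))
  for (cmp in clock_cols) {
    expect_equal(a[[cmp]], b[[cmp]], tolerance = 1e-4)
  }
  # and the cascade states do differ between the two runs
  expect_gt(max(abs(a$TS1 - b$TS1)), 1)
})

test_that("integration failures name the offending component and time", {
  # vd_hsp = 0 sends indHSP off its balance; vb_hsp = 0 starves it to 0
  p <- clock_params(vb_hsp = 0)
  expect_error(simulate_cell(p, constant_schedule(37), t_end = 200))
})
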