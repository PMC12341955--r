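# thermoclock

Temperature is a potent zeitgeber: square-wave temperature cycles that
mimic body-temperature rhythms can entrain the circadian clocks of
peripheral cells in culture. `thermoclock` is an R package for simulating
that process and for studying what happens when the rhythm is weakened,
detuned, or alternated "shift-work"-style.

The core is a semi-mechanistic ODE model of one cell (11 states): a
thermosensing cascade (TS1 integrates the temperature's magnitude and
deviation, `dTS1/dt = vact0·Tavg + vact1·(T − Tavg) − vina·TS1`; TS2 is
its Hill-saturated effector) feeds an HSF1/HSP heat-shock-response module
(TS2 stimulates HSF1 activation; induced HSP inhibits it and its own
production), and active HSF1 multiplies *Per/Cry* transcription in a
Becker–Weimann-style clock gene network through a saturable entrainment
factor with HSP competition. On top of single cells the package provides:

* **Schedules** — constant, square-wave (normal/reversed = 12 h
  translates), and alternating shift schedules in the `"N-n1:n2"` grammar
  (`"28-5:2"` = 20 d reversed + 8 d normal, repeating), evaluated exactly
  via piecewise integration with solver restarts at every temperature
  jump (compiled C right-hand side through deSolve).
* **Populations** — heterogeneous cells Sobol-sampled around the nominal
  parameters; individual "subjects" differing in their thermosensing
  triple (`vact0_ts1`, `vact1_ts1`, `kb_ts2`).
* **Metrics** — peak-based periods and phases (warm-onset reference,
  ZT0), and the mean-field synchronization index
  `R_syn = Var_t(ȳ) / mean_i Var_t(y_i)` ∈ [0, 1], globally or in
  sliding windows.
* **Experiments** — rhythm on/off validation, amplitude (0–5 °C) and mean
  (32–40 °C) sweeps, an Arnold entrainment grid on the period × amplitude
  plane, shift-schedule adaptation runs, and an individualized-response
  sweep with an OLS sensitivity regression
  (`R_syn ~ vact0_ts1 + vact1_ts1 + kb_ts2`), with broom-style `tidy()` /
  `glance()` methods and `autoplot()` views throughout.

## A worked example

```r
library(thermoclock)

# one nominal cell under a 12 h warm / 12 h cold 37 +/- 1.5 degC cycle
traj <- simulate_cell(t_end = 1200)
period_of(traj$PerCry_mRNA, traj$time_h, burn_in = 480)
#> [1] 24.00131
phase_of(traj$PerCry_mRNA, traj$time_h, burn_in = 480)
#> [1] 14.10623

# its free-running intrinsic period, clock decoupled from the cascade
free <- simulate_cell(clock_params(khsf1 = 0), constant_schedule(37),
                      t_end = 1200)
period_of(free$PerCry_mRNA, free$time_h, burn_in = 480)
#> [1] 23.84257

# a 200-cell heterogeneous population under the same rhythm
pop <- sample_population(200, seed = 0)
ens <- simulate_population(pop, pattern_schedule(), t_end = 1680,
                           keep = c("actHSF1", "PerCry_mRNA"))
r_syn(ens, "PerCry_mRNA", window = c(480, 1680))
#> [1] 0.8950849
r_syn(ens, "actHSF1", window = c(480, 1680))
#> [1] 0.9842684

# shift work: 50 d normal pattern, then 7-5:2 (5 d reversed : 2 d normal)
ass <- run_ass("7-5:2", n_cells = 200, pre_days = 50, post_days = 100,
               seed = 0)
ass$summary[, c("phase_shift_h", "mean_post_r_syn")]
#> # A tibble: 1 × 2
#>   phase_shift_h mean_post_r_syn
#>           <dbl>           <dbl>
#> 1         -10.8           0.585
```

The single cell entrains to exactly 24 h and peaks ~14 h after warm onset;
decoupled, it free-runs at ~23.8 h. The population synchronizes strongly
(R_syn 0.90 for the clock marker; 0.98 for the cascade output, which
tracks temperature directly). Under the 7-5:2 alternating schedule the
ensemble adopts the reversed (dominant) pattern's phase — a ~11 h phase
advance, reported in [−12, 12) h — while keeping partial synchronization
(mean 24 h-windowed R_syn ≈ 0.58); see the vignette for why the adopted
phase sits ~1 h short of a complete −12 h inversion.

A thin CLI wraps the same functions
(`exec/thermoclock <command> --config cfg.yaml --seed 0 --out-dir out/`),
writing CSV tables and a hash-stamped run manifest.

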