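# shared, lazily computed fixtures (each built at most once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# nominal cell entrained by the W12/C12 37 +/- 1.5 pattern
entrained_traj <- function() {
  fixture("entrained", function() simulate_cell(t_end = 1200))
}

# small heterogeneous population under the nominal rhythm
small_rhythmic_ensemble <- function() {
  fixture("small_ens", function() {
    simulate_population(sample_population(12, seed = 7),
                        pattern_schedule(), t_end = 960,
                        keep = c("actHSF1", "PerCry_mRNA"))
  })
}
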