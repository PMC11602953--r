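# Small in-code fixtures shared across test files.

# a tiny complete two-patient CSV in the package's long dialect
write_toy_csv <- function(path) {
  writeLines(c(
    "subject,arm,visit,outcome,baseline,offtrt",
    "p1,reference,1,1.5,10,0",
    "p1,reference,2,2.5,10,0",
    "p2,active,1,0.5,12,0",
    "p2,active,2,1.0,12,0"), path)
  path
}

# hand-built trial: 4 patients, 3 visits, one deviator who stops, one who
# continues off treatment
small_trial <- function() {
  y <- rbind(c(1, 2, 3),
             c(2, 3, 4),
             c(1, 2, NA),   # deviates after visit 2 and stops
             c(2, 1, 0))    # deviates after visit 1, observed off treatment
  trial_data(y, arm = c(0, 1, 1, 0), baseline = c(10, 12, 11, 9),
             deviation_visit = c(3, 3, 2, 1))
}

# covered-style synthetic layout used by the heavier pipeline tests
covered_fixture <- function(seed = 1, n = c(60, 60)) {
  cfg <- synthetic_config(n_per_arm = n,
                          dev_hazard = rbind(c(0.10, 0.10, 0.15),
                                             c(0.10, 0.10, 0.15)))
  generate_trial(cfg, seed = seed)
}

fast_gibbs <- function(seed = 1, K = 60, burn = 150)
  gibbs_config(n_burn = burn, n_draws = K, seed = seed)
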