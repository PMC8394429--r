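# shared fixtures: reference per-ST parameters and model-generated series

ref_table <- default_params_table()

ref_params <- function(st) default_params_for_st(st)

design_times <- c(seq(0, 120, by = 15), 2600)

# noiseless trajectory of one condition at the standard weighing times
noiseless_series <- function(p, st = NA_real_, times = design_times) {
  moisture_series(times, moisture_at_time(p, times), st_h = st)
}

# a handful of valid random parameter sets for property-style loops
random_params <- function(n, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    me <- runif(1, 0, 20)
    kinetic_params(m0 = runif(1, me + 5, 100), me = me,
                   k = runif(1, 1e-3, 0.1))
  })
}
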