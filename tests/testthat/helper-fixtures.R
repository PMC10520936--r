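# Shared fixtures for the suite. Heavier simulations are computed lazily
# and cached for reuse across test files within one run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

rat_config <- function() cached("rat_cfg", default_config("rat_neostriatal"))
gp_config <- function() cached("gp_cfg", default_config("guinea_pig_ventricular"))

# a random positive composite-rate vector for cycle-model cross-checks
random_rates <- function() {
  structure(as.list(setNames(10^runif(8, -2, 2),
                             c("R1p", "R2p", "R3p", "R4p",
                               "R1m", "R2m", "R3m", "R4m"))),
            class = "thz_cycle_rates")
}

# short coarse stimulated run shared by conservation / qualitative tests
mini_run <- function() {
  cached("mini_run", {
    mc <- mini_config(scale = 0.5)
    run_simulation(mc$config, mc$plan)
  })
}

# the full-scale reference run (5e7 V/m, 0.5 THz, 1.2 ns on, 12.3 ns)
reference_run <- function() {
  cached("reference_run", {
    cfg <- rat_config()
    train <- pulse_train(E0 = 5e7, f_rep = 0.5e12, duty = 0.5,
                         t_on = 1.2e-9)
    plan <- simulation_plan(train, t_end = 12.3e-9, n_frames = 300,
                            experiment = "reference")
    run_simulation(cfg, plan)
  })
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.xmin)), tol)
}
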