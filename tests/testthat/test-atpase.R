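test_that("composite rate edge cases follow the printed forms", {
  cfg <- rat_config()
  ap <- cfg$atpase
  conc <- initial_concentrations(cfg)

  # no intracellular Na to bind: forward phosphorylation shuts off
  r0 <- cycle_rates(-0.06, 0, conc$c_Na_o, conc$c_K_i, conc$c_K_o, ap)
  expect_equal(r0$R1p, 0)

  # MgATP saturation: R4p -> k4p, and R3m -> 0
  apS <- ap; apS$c_MgATP <- 1e9
  rS <- cycle_rates(-0.06, conc$c_Na_i, conc$c_Na_o, conc$c_K_i,
                    conc$c_K_o, apS)
  expect_equal(rS$R4p, ap$k4p, tolerance = 1e-6)
  expect_lt(rS$R3m, 1e-6)

  # no extracellular K: forward K binding off
  rK <- cycle_rates(0.02, conc$c_Na_i, conc$c_Na_o, conc$c_K_i, 0, ap)
  expect_equal(rK$R3p, 0)

  expect_error(cycle_rates(0, -1, 1, 1, 1, ap), "non-negative")
})

test_that("full rate vector matches an independent symbolic evaluation", {
  cfg <- rat_config()
  ap <- cfg$atpase
  cn <- physical_constants(310)
  Vm <- -0.06
  ci <- list(na = 12, k = 139); co <- list(na = 145, k = 4)
  fv <- cn$F * Vm / (cn$R_u * 310)
  # written out from scratch, term by term
  nai <- (12 / ap$kd_Nai0) * exp(-ap$d_Nai * fv)
  nao <- (145 / ap$kd_Nao0) * exp(-ap$d_Nao * fv)
  ki <- (139 / ap$kd_Ki0) * exp(-ap$d_Ki * fv)
  ko <- (4 / ap$kd_Ko0) * exp(-ap$d_Ko * fv)
  atp <- ap$c_MgATP / ap$kd_MgATP
  expected <- list(
    R1p = ap$k1p * nai^3 / ((1 + nai)^3 + (1 + ki)^2 - 1),
    R2p = ap$k2p,
    R3p = ap$k3p * ko^2 / ((1 + nao)^3 + (1 + ko)^2 - 1),
    R4p = ap$k4p * atp / (1 + atp),
    R1m = ap$k1m * ap$c_MgADP,
    R2m = ap$k2m * nao^3 / ((1 + nao)^3 + (1 + ko)^2 - 1),
    R3m = ap$k3m * ap$c_P * 10^(3 - ap$pH) / (1 + atp),
    R4m = ap$k4m * ki^2 / ((1 + nai)^3 + (1 + ki)^2 - 1)
  )
  got <- cycle_rates(Vm, 12, 145, 139, 4, ap, cn, 310)
  for (nm in names(expected)) {
    expect_equal(got[[nm]], expected[[nm]], tolerance = 1e-12,
                 label = nm)
  }
})

test_that("closed-form cycle rate equals the 4-state stationary-flux oracle", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    r <- random_rates()
    v <- cycle_rate(r)
    v_oracle <- cycle_steady_state_oracle(r)
    worst <- max(worst, abs(v - v_oracle) /
                   max(abs(v_oracle), .Machine$double.xmin))
  }
  expect_lt(worst, 1e-10)
})

test_that("cycle rate sign logic: stall at balanced products, forward when backward is null", {
  r <- random_rates()
  # rescale backward rates so the products balance -> thermodynamic stall
  fwd <- r$R1p * r$R2p * r$R3p * r$R4p
  bwd <- r$R1m * r$R2m * r$R3m * r$R4m
  r$R1m <- r$R1m * (fwd / bwd)
  expect_equal(cycle_rate(r), 0, tolerance = 1e-18)

  r0 <- random_rates()
  r0$R1m <- r0$R2m <- r0$R3m <- r0$R4m <- 0
  expect_gt(cycle_rate(r0), 0)
})

test_that("pump current, per-theta flows and power obey the exact stoichiometry", {
  cfg <- rat_config()
  cn <- physical_constants()
  grid <- theta_grid(cfg$geometry)
  expect_equal(pump_current(0, cfg$atpase$F_c), 0)
  expect_equal(pump_current(50, 2e-12), 2 * pump_current(50, 1e-12))

  I <- 4e-11
  fl <- pump_flows_theta(I, grid$A_theta, grid$A_cell, cn)
  expect_equal(fl$J_Na_total, 3 * I / cn$q_ele / cn$N_A)
  expect_equal(fl$J_K_total, -2 * I / cn$q_ele / cn$N_A)
  expect_equal(sum(fl$J_Na), fl$J_Na_total, tolerance = 1e-14)
  expect_equal(fl$J_K / fl$J_Na, rep(-2 / 3, 13), tolerance = 1e-14)
  expect_equal(2 * fl$J_Na_total + 3 * fl$J_K_total, 0)

  expect_equal(pump_power(0, cn), 0)
  expect_equal(pump_power(I, cn, "per_molecule") / pump_power(I, cn),
               cn$N_A)
  expect_equal(pump_power(2 * I, cn), 2 * pump_power(I, cn))
})

test_that("pump runs forward at rest: Na out, K in", {
  for (cfg in list(rat_config(), gp_config())) {
    conc <- initial_concentrations(cfg)
    r <- cycle_rates(cfg$electrical$V_rest, conc$c_Na_i, conc$c_Na_o,
                     conc$c_K_i, conc$c_K_o, cfg$atpase)
    I <- pump_current(cycle_rate(r), cfg$atpase$F_c)
    grid <- theta_grid(cfg$geometry)
    fl <- pump_flows_theta(I, grid$A_theta, grid$A_cell)
    expect_gt(fl$J_Na_total, 0)
    expect_lt(fl$J_K_total, 0)
    expect_gt(pump_power(I, cfg$constants, "per_molecule"), 0)
  }
})

test_that("I-V curves have the described shapes for the two cell types", {
  rat <- rat_config(); gp <- gp_config()
  vg <- seq(-0.12, 0.06, by = 0.002)
  iv_rat <- iv_curve(rat$atpase, initial_concentrations(rat), vg)
  iv_gp <- iv_curve(gp$atpase, initial_concentrations(gp), vg)
  # monotone non-decreasing over the physiological window (rat)
  expect_true(all(diff(iv_rat$I) > -1e-18))
  # inhibition at overlarge positive excursions: a bell over a wide range
  wide <- iv_curve(rat$atpase, initial_concentrations(rat),
                   seq(-0.2, 1.0, by = 0.01))
  expect_lt(wide$I[wide$Vm == 1.0], 0.01 * max(wide$I))
  # guinea pig: narrower shape, peak shifted toward more negative Vm
  wide_gp <- iv_curve(gp$atpase, initial_concentrations(gp),
                      seq(-0.2, 1.0, by = 0.01))
  peak_rat <- wide$Vm[which.max(wide$I)]
  peak_gp <- wide_gp$Vm[which.max(wide_gp$I)]
  expect_lt(peak_gp, peak_rat)
  width_at <- function(iv) {
    keep <- iv$I > 0.5 * max(iv$I)
    diff(range(iv$Vm[keep]))
  }
  expect_lt(width_at(wide_gp), width_at(wide))
  # zero external K suppresses the forward branch at positive Vm
  conc0 <- initial_concentrations(rat); conc0$c_K_o <- 0
  iv0 <- iv_curve(rat$atpase, conc0, vg)
  expect_true(all(iv0$I <= 0))
})

test_that("a reversal crossing exists when backward products can dominate", {
  cfg <- rat_config()
  ap <- cfg$atpase
  ap$c_MgADP <- 40; ap$c_P <- 400  # product-loaded cytoplasm
  conc <- initial_concentrations(cfg)
  vg <- seq(-0.3, 0.1, by = 0.002)
  iv <- iv_curve(ap, conc, vg)
  expect_lt(min(iv$I), 0)
  expect_gt(max(iv$I), 0)
  # bracket scan finds a sign change
  expect_true(any(diff(sign(iv$I)) != 0))
})

test_that("the voltage-exponential clamp does not engage below |Vm| = 1 V", {
  cfg <- rat_config()
  conc <- initial_concentrations(cfg)
  expect_no_warning(
    cycle_rates(seq(-1, 1, by = 0.05), conc$c_Na_i, conc$c_Na_o,
                conc$c_K_i, conc$c_K_o, cfg$atpase))
  w <- testthat::capture_warnings(
    cycle_rates(60, conc$c_Na_i, conc$c_Na_o, conc$c_K_i, conc$c_K_o,
                cfg$atpase))
  expect_match(w, "clamped", all = FALSE)
})

test_that("fit_iv with no free parameters returns the guess with residuals", {
  cfg <- rat_config()
  conc <- initial_concentrations(cfg)
  ds <- make_iv_dataset(cfg$atpase, conc, noise_frac = 0.05, seed = 4)
  out <- fit_iv(ds$data, cfg$atpase, conc, free = character(0))
  expect_identical(out$par, cfg$atpase)
  expect_length(out$residuals, nrow(ds$data))
  expect_true(out$converged)
})

test_that("noiseless synthetic I-V recovers F_c to better than 0.1%", {
  cfg <- rat_config()
  conc <- initial_concentrations(cfg)
  true_par <- cfg$atpase
  ds <- make_iv_dataset(true_par, conc, noise_frac = 0, seed = 1)
  start <- true_par; start$F_c <- true_par$F_c * 2.5
  out <- fit_iv(ds$data, start, conc, free = "F_c", n_starts = 3,
                seed = 2)
  expect_lt(abs(out$par$F_c - true_par$F_c) / true_par$F_c, 1e-3)
})
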