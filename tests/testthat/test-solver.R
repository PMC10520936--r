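test_that("zero field and zero Vm give identically zero potentials and currents", {
  cfg <- rat_config()
  op <- field_operator(cfg$geometry, cfg$electrical)
  sol <- solve_potential(op, rep(0, 13), 0, cfg$geometry)
  expect_equal(max(abs(sol$Phi_in)), 0, tolerance = 1e-18)
  expect_equal(max(abs(sol$Phi_out)), 0, tolerance = 1e-18)
  expect_equal(max(abs(sol$J_n)), 0, tolerance = 1e-18)
})

test_that("uniform Vm at zero field is spherically symmetric with zero current", {
  cfg <- rat_config()
  op <- field_operator(cfg$geometry, cfg$electrical)
  sol <- solve_potential(op, rep(cfg$electrical$V_rest, 13), 0,
                         cfg$geometry)
  # no theta dependence anywhere
  expect_lt(max(apply(sol$Phi_in, 1, function(r) diff(range(r)))), 1e-15)
  expect_lt(max(apply(sol$Phi_out, 1, function(r) diff(range(r)))), 1e-15)
  # a uniform membrane voltage draws no bulk conduction current
  # (round-off scale: matrix entries are O(1e6) S/m^2)
  expect_lt(max(abs(sol$J_n)), 1e-8)
})

test_that("returned potentials satisfy Laplace under an independent FD stencil", {
  # independent oracle: axisymmetric spherical Laplacian
  # Phi_rr + (2/r) Phi_r + (1/r^2)(Phi_tt + cot(theta) Phi_t)
  # applied with second-order central differences to the solved exterior
  # field of a random admissible input, on a fine probe grid away from the
  # axis. Scale: residual * h^-2 terms compare against the field scale.
  cfg <- rat_config()
  geom <- cfg$geometry
  geom$N_r_out <- 81
  geom$N_theta <- 49   # fine probe grid so stencil truncation is small
  op <- field_operator(geom, cfg$electrical)
  set.seed(7)
  Vm <- cfg$electrical$V_rest + 0.05 * sin(2 * op$grid$theta)
  E0 <- 2e4
  sol <- solve_potential(op, Vm, E0, geom)

  r <- sol$r_out
  th <- sol$theta
  hr <- diff(r)[1]; ht <- diff(th)[1]
  Phi <- sol$Phi_out
  ir <- 2:(length(r) - 1); it <- 3:(length(th) - 2)  # interior, off-axis
  Prr <- (Phi[ir + 1, it] - 2 * Phi[ir, it] + Phi[ir - 1, it]) / hr^2
  Pr  <- (Phi[ir + 1, it] - Phi[ir - 1, it]) / (2 * hr)
  Ptt <- (Phi[ir, it + 1] - 2 * Phi[ir, it] + Phi[ir, it - 1]) / ht^2
  Pt  <- (Phi[ir, it + 1] - Phi[ir, it - 1]) / (2 * ht)
  rmat <- matrix(r[ir], length(ir), length(it))
  cot <- matrix(cos(th[it]) / sin(th[it]), length(ir), length(it),
                byrow = TRUE)
  resid <- Prr + 2 / rmat * Pr + (Ptt + cot * Pt) / rmat^2
  scale <- max(abs(Phi)) / hr^2
  expect_lt(max(abs(resid)) / scale, 1e-3)
})

test_that("outer boundary carries the applied uniform-field potential", {
  cfg <- rat_config()
  op <- field_operator(cfg$geometry, cfg$electrical)
  Vm <- rep(cfg$electrical$V_rest, 13)
  E0 <- 1e5
  sol <- solve_potential(op, Vm, E0, cfg$geometry)
  outer_phi <- sol$Phi_out[nrow(sol$Phi_out), ]
  expect_equal(outer_phi, -E0 * cfg$geometry$R_domain * cos(sol$theta),
               tolerance = 1e-10)
  # the interface jump reproduces Vm at the nodes
  inner_face <- sol$Phi_in[nrow(sol$Phi_in), ]
  outer_face_at_R <- sol$Phi_out[1, ]
  expect_equal(inner_face - outer_face_at_R, Vm, tolerance = 1e-12)
})

test_that("membrane relaxes to rest exponentially at rate g1/C_m", {
  cfg <- rat_config()
  el <- cfg$electrical
  Vm <- rep(el$V_rest + 0.05, 13)
  dt <- 1e-6
  n <- 200
  for (i in seq_len(n)) {
    Vm <- step_membrane_potential(Vm, 0, 0, el, dt)
  }
  # closed-form RC decay oracle (exact discrete Euler solution)
  expected <- el$V_rest + 0.05 * (1 - dt * el$g1 / el$C_m)^n
  expect_equal(Vm, rep(expected, 13), tolerance = 1e-12)
  # rest is a fixed point
  Vr <- step_membrane_potential(rep(el$V_rest, 13), 0, 0, el, 1e-9)
  expect_equal(Vr, rep(el$V_rest, 13))
})

test_that("numeric charging matches the spherical-cell closed form within 2%", {
  cfg <- rat_config()
  el <- cfg$electrical; geom <- cfg$geometry
  op <- field_operator(geom, el)
  E0 <- 1e5
  dt <- 1e-10
  tau <- geom$R_cell * el$C_m * (1 / el$sigma_i + 1 / (2 * el$sigma_o))
  nt <- ceiling(5 * tau / dt)
  Vm <- rep(el$V_rest, 13)
  checks <- round(c(0.5, 1, 2, 5) * tau / dt)
  worst <- 0
  for (i in seq_len(nt)) {
    J_n <- as.numeric(op$M %*% Vm + op$w * E0)
    Vm <- step_membrane_potential(Vm, J_n, 0, el, dt)
    if (i %in% checks) {
      ana <- schwan_reference(E0, geom$R_cell, el$sigma_i, el$sigma_o,
                              el$C_m, el$g1, i * dt, op$grid$theta,
                              V_rest = el$V_rest)
      worst <- max(worst, max(abs(Vm - ana)) / (1.5 * E0 * geom$R_cell))
    }
  }
  expect_lt(worst, 0.02)
})

test_that("theta = pi/2 stays at rest under axial stimulation with pores closed", {
  cfg <- rat_config()
  op <- field_operator(cfg$geometry, cfg$electrical)
  tr <- pulse_train(E0 = 5e7, f_rep = 0.5e12, t_on = 0.2e-9)
  Vm <- rep(cfg$electrical$V_rest, 13)
  dt <- 5e-14
  drift <- 0
  for (i in 1:4000) {
    E <- field_at(tr, (i - 1) * dt)
    J_n <- as.numeric(op$M %*% Vm + op$w * E)
    Vm <- step_membrane_potential(Vm, J_n, 0, cfg$electrical, dt)
    drift <- max(drift, abs(Vm[7] - cfg$electrical$V_rest))
  }
  expect_lt(drift, 1e-9)
  expect_gt(abs(Vm[1] - cfg$electrical$V_rest), 0.05)  # poles do charge
})

test_that("grid refinement leaves the charged membrane profile unchanged", {
  cfg <- rat_config()
  run_peak <- function(N_theta) {
    geom <- cfg$geometry; geom$N_theta <- N_theta
    op <- field_operator(geom, cfg$electrical)
    Vm <- rep(cfg$electrical$V_rest, N_theta)
    dt <- 2e-10
    for (i in 1:600) {
      J_n <- as.numeric(op$M %*% Vm + op$w * 1e5)
      Vm <- step_membrane_potential(Vm, J_n, 0, cfg$electrical, dt)
    }
    Vm[1]
  }
  expect_equal(run_peak(13), run_peak(25), tolerance = 0.01)
})

test_that("explicit stability bound violations raise an advisory error", {
  cfg <- rat_config()
  op <- field_operator(cfg$geometry, cfg$electrical)
  expect_error(
    step_membrane_potential(rep(0, 13), 0, 0, cfg$electrical,
                            dt = 2 * op$dt_stable,
                            dt_max = op$dt_stable),
    "reduce the time step")
})

test_that("membrane conductivity diagnostic follows I_p/Vm with a floored fallback", {
  expect_equal(membrane_conductivity(rep(0, 5), rep(0, 5)), rep(0, 5))
  expect_equal(membrane_conductivity(c(2, 4), c(0.5, 0.5)), c(4, 8))
  # below the floor voltage the geometric estimate is used
  expect_equal(membrane_conductivity(1e-9, 1e-6, g_geom = 3), 3)
  # doubling open area doubles the estimate (linearity via f_p)
  cfg <- rat_config()
  ci <- matrix(vapply(cfg$species, `[[`, numeric(1), "c_i0"), 4, 1)
  co <- matrix(vapply(cfg$species, `[[`, numeric(1), "c_o0"), 4, 1)
  g1x <- pore_conductance_estimate(cfg$species, ci, co, 0.01,
                                   cfg$geometry$d_mem, 310)
  g2x <- pore_conductance_estimate(cfg$species, ci, co, 0.02,
                                   cfg$geometry$d_mem, 310)
  expect_equal(g2x, 2 * g1x)
})
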