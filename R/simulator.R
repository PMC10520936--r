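# Coupled whole-cell simulation loop: stimulus -> potential solve ->
# membrane charging -> pore step -> pore fluxes -> pump -> concentration
# update, with a piecewise dt schedule (fine steps while the drive varies,
# geometric relaxation afterwards) and trajectory recording.

#' Build a simulation plan
#'
#' @param train a [pulse_train()] (its `t_on` is the stimulation
#'   duration).
#' @param t_end total simulated time, s.
#' @param dt_stim time step during stimulation, s; default 1/20 of the
#'   pulse width.
#' @param dt_growth geometric growth factor of dt after stimulation.
#' @param dt_cap_factor post-stimulation dt cap as a multiple of
#'   `dt_stim`.
#' @param n_frames number of stored trajectory frames.
#' @param experiment free-text tag recorded in the trajectory.
#' @return List of class `thz_plan`.
#' @export
simulation_plan <- function(train, t_end,
                            dt_stim = pulse_width(train) / 20,
                            dt_growth = 1.05, dt_cap_factor = 100,
                            n_frames = 400, experiment = "run") {
  stopifnot(t_end > train$t_on, dt_stim > 0, dt_growth > 1,
            dt_cap_factor >= 1, n_frames >= 2)
  structure(list(train = train, t_end = t_end, dt_stim = dt_stim,
                 dt_growth = dt_growth, dt_cap_factor = dt_cap_factor,
                 n_frames = n_frames, experiment = experiment),
            class = "thz_plan")
}

#' Run the coupled whole-cell simulation
#'
#' Advances the coupled system — applied pulse-train field, quasi-static
#' potential, per-theta membrane potential, hydrophilic-pore population,
#' modified-PNP pore fluxes, Na+,K+-ATPase flows and power, and
#' compartment concentrations — from rest to `plan$t_end`. The update is
#' deterministic: identical inputs give bit-identical trajectories. If a
#' concentration update would go negative the whole physics step is redone
#' at half the step (the configured `negative_conc = "substep"` policy);
#' `"clamp"` clamps with a warning instead.
#'
#' @param config a `thz_config` bundle.
#' @param plan a [simulation_plan()].
#' @param pores,pump logical switches disabling the electroporation or
#'   pump subsystem (used for solver validation runs).
#' @return A `thz_trajectory`: list with `t` (frame times), per-theta
#'   matrices `Vm`, `g_m`, `N`, `count`, `mean_radius`, `f_p`, `I_theta`,
#'   `P_theta` (frames x N_theta), species arrays `J_pore`, `J_pump`,
#'   `c_i`, `c_o` (frames x 4 x N_theta), whole-cell series `A_p`,
#'   `I_cell`, `P_cell` (per-molecule mode), `P_cell_literal`, and `meta`.
#' @export
run_simulation <- function(config, plan, pores = TRUE, pump = TRUE) {
  stopifnot(inherits(config, "thz_config"), inherits(plan, "thz_plan"))
  geom <- config$geometry; el <- config$electrical
  pr <- config$pore; ap <- config$atpase; opts <- config$options
  cn <- config$constants; T <- el$T
  train <- plan$train
  grid <- theta_grid(geom)
  op <- field_operator(geom, el)
  K <- geom$N_theta
  sv <- species_vectors(config$species)
  ns <- length(sv$z)

  Vm <- rep(el$V_rest, K)
  st <- pore_state_init(grid, pr, opts, T, resting_cohorts = pores)
  c_i <- matrix(vapply(config$species, `[[`, numeric(1), "c_i0"), ns, K)
  c_o <- matrix(vapply(config$species, `[[`, numeric(1), "c_o0"), ns, K)
  rownames(c_i) <- rownames(c_o) <- sv$name
  I_p <- numeric(K)
  J_pore <- J_pump <- matrix(0, ns, K)
  rownames(J_pump) <- sv$name
  v_cyc_th <- numeric(K)
  iNa <- which(sv$name == "Na"); iK <- which(sv$name == "K")

  nf <- plan$n_frames
  rec <- list(
    t = numeric(nf), Vm = matrix(0, nf, K), g_m = matrix(0, nf, K),
    N = matrix(0, nf, K), count = matrix(0, nf, K),
    mean_radius = matrix(NA_real_, nf, K), f_p = matrix(0, nf, K),
    I_theta = matrix(0, nf, K), P_theta = matrix(0, nf, K),
    J_pore = array(0, c(nf, ns, K)), J_pump = array(0, c(nf, ns, K)),
    c_i = array(0, c(nf, ns, K)), c_o = array(0, c(nf, ns, K)),
    A_p = numeric(nf), I_cell = numeric(nf), P_cell = numeric(nf),
    P_cell_literal = numeric(nf)
  )
  rec_times <- seq(0, plan$t_end, length.out = nf)
  frame <- 0L

  pump_scale_na <- 3 / (cn$q_ele * cn$N_A * grid$A_cell)  # mol/s per A, per m^2
  dt_cap <- plan$dt_stim * plan$dt_cap_factor
  area_frac <- grid$A_theta / grid$A_cell
  substep_mode <- identical(opts$negative_conc, "substep")
  limit_active <- FALSE

  # evaluate the dependent quantities once at the initial state so the
  # first recorded frame carries the resting fluxes/pump level
  if (pores) {
    f_p0 <- st$A_p_theta / grid$A_theta
    Jd0 <- gmpnp_flux_density(config$species, c_i, c_o, Vm, geom$d_mem,
                              T, cn)
    pf0 <- pore_flux(Jd0, f_p0, config$species, cn)
    J_pore <- pf0$J_pore; I_p <- pf0$I_p
  }
  if (pump) {
    r0 <- cycle_rates(Vm, c_i[iNa, ], c_o[iNa, ], c_i[iK, ], c_o[iK, ],
                      ap, cn, T)
    v_cyc_th <- cycle_rate(r0)
    j_na0 <- ap$F_c * v_cyc_th * pump_scale_na
    J_pump[iNa, ] <- j_na0
    J_pump[iK, ] <- -2 / 3 * j_na0
  }

  t <- 0; dt_relax <- plan$dt_stim
  record_frame <- function(rec, frame, t) {
    ps <- pore_summary(st)
    g_geom <- pore_conductance_estimate(config$species, c_i, c_o, ps$f_p,
                                        geom$d_mem, T, cn)
    rec$t[frame] <- t
    rec$Vm[frame, ] <- Vm
    rec$g_m[frame, ] <- membrane_conductivity(I_p, Vm, g_geom)
    rec$N[frame, ] <- st$N
    rec$count[frame, ] <- ps$count
    rec$mean_radius[frame, ] <- ps$mean_radius
    rec$f_p[frame, ] <- ps$f_p
    I_th <- ap$F_c * v_cyc_th * area_frac
    rec$I_theta[frame, ] <- I_th
    rec$P_theta[frame, ] <- pump_power(I_th, cn, "per_molecule")
    rec$J_pore[frame, , ] <- J_pore
    rec$J_pump[frame, , ] <- J_pump
    rec$c_i[frame, , ] <- c_i
    rec$c_o[frame, , ] <- c_o
    rec$A_p[frame] <- st$A_p
    Icell <- sum(I_th)
    rec$I_cell[frame] <- Icell
    rec$P_cell[frame] <- pump_power(Icell, cn, "per_molecule")
    rec$P_cell_literal[frame] <- pump_power(Icell, cn, "literal")
    rec
  }

  while (t < plan$t_end - 1e-18) {
    if (frame < nf && t >= rec_times[frame + 1] - 1e-18) {
      frame <- frame + 1L
      rec <- record_frame(rec, frame, t)
    }
    stim <- t < train$t_on
    dt <- if (stim) min(plan$dt_stim, train$t_on - t) else {
      dt_relax <- min(dt_relax * plan$dt_growth, dt_cap)
      min(dt_relax, plan$t_end - t)
    }

    snap <- list(Vm = Vm, st = st, c_i = c_i, c_o = c_o, I_p = I_p)
    repeat {
      E <- if (stim) field_at(train, t) else 0
      J_n <- as.numeric(op$M %*% Vm + op$w * E)
      i_pump <- if (pump && isTRUE(opts$include_pump_current_in_vm))
        ap$F_c * v_cyc_th / grid$A_cell else 0
      Vm <- step_membrane_potential(Vm, J_n, I_p + i_pump, el, dt)

      if (pores) {
        st <- step_pores(st, Vm, dt, pr, T)
        f_p <- st$A_p_theta / grid$A_theta
        Jd <- gmpnp_flux_density(config$species, c_i, c_o, Vm,
                                 geom$d_mem, T, cn)
        pf <- pore_flux(Jd, f_p, config$species, cn)
        J_pore <- pf$J_pore; I_p <- pf$I_p
      }

      if (pump) {
        r <- cycle_rates(Vm, c_i[iNa, ], c_o[iNa, ], c_i[iK, ],
                         c_o[iK, ], ap, cn, T)
        v_cyc_th <- cycle_rate(r)
        j_na <- ap$F_c * v_cyc_th * pump_scale_na        # mol/(m^2 s)
        J_pump[iNa, ] <- j_na
        J_pump[iK, ] <- -2 / 3 * j_na
      }

      upd <- tryCatch(
        update_concentrations(c_i, c_o, J_pore + J_pump, grid, dt,
                              bath = opts$extracellular_bath,
                              negative = if (!substep_mode) "clamp"
                                         else if (limit_active) "limit"
                                         else "error"),
        error = function(e) e)
      if (inherits(upd, "error")) {
        if (!substep_mode)
          stop("concentration update failed: ", conditionMessage(upd))
        if (dt > plan$dt_stim / 4) {
          # transient overshoot: redo the whole physics step at dt/2
          Vm <- snap$Vm; st <- snap$st; c_i <- snap$c_i; c_o <- snap$c_o
          I_p <- snap$I_p
          dt <- dt / 2
          next
        }
        # a drained compartment under sustained outward drift: halving
        # cannot cure the sign; switch to the donor-limited update (it is
        # identical to the plain update whenever nothing would go
        # negative, so this is a safe permanent fallback)
        limit_active <- TRUE
        upd <- update_concentrations(c_i, c_o, J_pore + J_pump, grid, dt,
                                     bath = opts$extracellular_bath,
                                     negative = "limit")
      }
      c_i <- upd$c_i; c_o <- upd$c_o
      break
    }
    t <- t + dt
  }
  if (frame < nf) {
    frame <- frame + 1L
    rec <- record_frame(rec, frame, t)
  }
  if (frame < nf) {
    keep <- seq_len(frame)
    rec$t <- rec$t[keep]; rec$A_p <- rec$A_p[keep]
    rec$I_cell <- rec$I_cell[keep]; rec$P_cell <- rec$P_cell[keep]
    rec$P_cell_literal <- rec$P_cell_literal[keep]
    for (nm in c("Vm", "g_m", "N", "count", "mean_radius", "f_p",
                 "I_theta", "P_theta"))
      rec[[nm]] <- rec[[nm]][keep, , drop = FALSE]
    for (nm in c("J_pore", "J_pump", "c_i", "c_o"))
      rec[[nm]] <- rec[[nm]][keep, , , drop = FALSE]
  }

  rec$meta <- list(config = config, plan = plan, theta = grid$theta,
                   species = sv$name, grid = grid,
                   pores = pores, pump = pump)
  class(rec) <- "thz_trajectory"
  rec
}

#' @export
print.thz_trajectory <- function(x, ...) {
  cat(sprintf("<thz_trajectory> '%s': %d frames to %.3g ns, %d theta nodes\n",
              x$meta$plan$experiment, length(x$t), max(x$t) * 1e9,
              length(x$meta$theta)))
  cat(sprintf("  peak |Vm| = %.3g V; final A_p/A_cell = %.3g; mean pump power = %.3g W\n",
              max(abs(x$Vm)), x$A_p[length(x$A_p)] / x$meta$grid$A_cell,
              mean(x$P_cell)))
  invisible(x)
}

#' Long-format data frame of the recorded per-theta series
#'
#' @param x a `thz_trajectory`.
#' @param ... unused.
#' @return data.frame with columns `t`, `theta`, `species`, `Vm`, `g_m`,
#'   `N`, `f_p`, `J_pore`, `J_pump`, `c_i`, `c_o`.
#' @export
as.data.frame.thz_trajectory <- function(x, ...) {
  nf <- length(x$t); K <- length(x$meta$theta); ns <- length(x$meta$species)
  out <- expand.grid(t = x$t, species = x$meta$species,
                     theta = x$meta$theta, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  idx_tk <- cbind(rep(seq_len(nf), times = ns * K),
                  rep(rep(seq_len(K), each = nf * ns)))
  out$Vm <- x$Vm[idx_tk]
  out$g_m <- x$g_m[idx_tk]
  out$N <- x$N[idx_tk]
  out$f_p <- x$f_p[idx_tk]
  idx3 <- cbind(rep(seq_len(nf), times = ns * K),
                rep(rep(seq_len(ns), each = nf), times = K),
                rep(seq_len(K), each = nf * ns))
  out$J_pore <- x$J_pore[idx3]
  out$J_pump <- x$J_pump[idx3]
  out$c_i <- x$c_i[idx3]
  out$c_o <- x$c_o[idx3]
  out
}

#' Write a trajectory to long-format CSV files
#'
#' Writes `<stem>_theta.csv` (per-theta long format) and `<stem>_avg.csv`
#' (unweighted theta-averaged series plus whole-cell pump current and
#' power).
#'
#' @param x a `thz_trajectory`.
#' @param stem output path stem.
#' @return The two paths, invisibly.
#' @export
write_trajectory_csv <- function(x, stem) {
  p1 <- paste0(stem, "_theta.csv"); p2 <- paste0(stem, "_avg.csv")
  utils::write.csv(as.data.frame(x), p1, row.names = FALSE)
  avg <- data.frame(t = x$t,
                    Vm = average_unweighted(x$Vm),
                    g_m = average_unweighted(x$g_m),
                    N = average_unweighted(x$N),
                    f_p = average_unweighted(x$f_p),
                    I_cell = x$I_cell, P_cell = x$P_cell,
                    P_cell_literal = x$P_cell_literal, A_p = x$A_p)
  for (s in seq_along(x$meta$species)) {
    avg[[paste0("J_pore_", x$meta$species[s])]] <-
      average_unweighted(x$J_pore[, s, ])
    avg[[paste0("c_i_", x$meta$species[s])]] <-
      average_unweighted(x$c_i[, s, ])
  }
  utils::write.csv(avg, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Detect the pore activation time
#'
#' First recorded time at which any theta node's pore density exceeds
#' `threshold * N0`.
#'
#' @param traj a `thz_trajectory`.
#' @param threshold multiple of the resting density `N0`; must exceed 1
#'   (at 1 the detector would fire at t = 0).
#' @return Time in seconds, or `NA` ("none") if never activated.
#' @export
detect_pore_activation <- function(traj, threshold = 10) {
  if (threshold <= 1)
    stop("threshold must exceed 1 (pore density starts at N0)")
  N0 <- traj$meta$config$pore$N0
  hit <- which(apply(traj$N > threshold * N0, 1, any))
  if (!length(hit)) return(NA_real_)
  traj$t[hit[1]]
}

#' Detect pump closure
#'
#' First time after the stimulation at which the whole-cell pump current
#' magnitude falls below `rel_threshold` times its post-stimulation
#' maximum and stays below for at least `hold` seconds.
#'
#' @param traj a `thz_trajectory`.
#' @param rel_threshold relative threshold.
#' @param hold sustained-below duration, s.
#' @return Time in seconds, or `NA` ("open") if the pump never closes
#'   within the recorded horizon.
#' @export
detect_pump_closure <- function(traj, rel_threshold = 1e-4, hold = 1e-9) {
  t_on <- traj$meta$plan$train$t_on
  post <- which(traj$t > t_on)
  if (!length(post)) return(NA_real_)
  Ia <- abs(traj$I_cell[post]); tt <- traj$t[post]
  thr <- rel_threshold * max(Ia)
  below <- Ia < thr
  for (i in seq_along(tt)) {
    if (!below[i]) next
    span <- which(tt >= tt[i] & tt <= tt[i] + hold)
    if (max(tt) < tt[i] + hold) return(NA_real_)  # horizon too short
    if (all(below[span])) {
      # require it to stay below through the hold window
      rest <- which(tt >= tt[i])
      first_up <- rest[which(!below[rest])[1]]
      if (is.na(first_up) || tt[first_up] > tt[i] + hold) return(tt[i])
    }
  }
  NA_real_
}

#' Frequency sweep at fixed duty cycle and field
#'
#' Runs the same plan at each repetition frequency (plus a no-stimulus
#' control) and reports the accumulated changes of the theta-averaged
#' intracellular concentrations at the end of the run together with the
#' averaged pump power series.
#'
#' @param config a `thz_config`.
#' @param frequencies repetition frequencies, Hz.
#' @param t_on stimulation duration, s.
#' @param t_end total simulated time, s.
#' @param E0 peak field, V/m.
#' @param duty duty cycle.
#' @param n_frames stored frames per run.
#' @param dt_divisor pulse-width divisor for the stimulation-phase step.
#' @return List with `table` (data.frame: `f_rep`, `dNa`, `dK`, `dCa`,
#'   `dCl` in mol/m^3; the control row has `f_rep = 0`), `power` (list of
#'   per-run data.frames `t`, `P`), and `runs` (the trajectories).
#' @export
frequency_sweep <- function(config, frequencies, t_on = 1.2e-9,
                            t_end = 12.3e-9, E0 = 5e7, duty = 0.5,
                            n_frames = 200, dt_divisor = 20) {
  run_one <- function(f, e0) {
    train <- pulse_train(E0 = e0, f_rep = f, duty = duty, t_on = t_on)
    plan <- simulation_plan(train, t_end,
                            dt_stim = pulse_width(train) / dt_divisor,
                            n_frames = n_frames,
                            experiment = sprintf("sweep_%.3gTHz", f / 1e12))
    run_simulation(config, plan)
  }
  runs <- lapply(frequencies, run_one, e0 = E0)
  ctrl <- run_one(frequencies[1], 0)
  all_runs <- c(runs, list(ctrl))
  c0 <- vapply(config$species, `[[`, numeric(1), "c_i0")
  dconc <- t(vapply(all_runs, function(tr) {
    nf <- length(tr$t)
    vapply(seq_along(c0), function(s)
      average_unweighted(tr$c_i[nf, s, ]) - c0[s], numeric(1))
  }, numeric(length(c0))))
  colnames(dconc) <- paste0("d", names(config$species))
  table <- cbind(data.frame(f_rep = c(frequencies, 0)),
                 as.data.frame(dconc))
  power <- lapply(all_runs, function(tr) data.frame(t = tr$t,
                                                    P = tr$P_cell))
  list(table = table, power = power, runs = all_runs)
}
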