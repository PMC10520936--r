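# Synthetic fixtures and independent analytic oracles: everything the test
# suite (and a user re-verifying an installation) needs without any
# external data.

#' Generate a synthetic whole-cell pump I-V dataset
#'
#' Evaluates the cycle-model I-V curve at known ("true") parameters and
#' adds seeded Gaussian noise scaled to a fraction of the maximum absolute
#' current — a stand-in for digitised whole-cell pump I-V measurements
#' that makes the fitting stage testable by parameter recovery.
#'
#' @param par true `atpase` parameter list.
#' @param conc concentrations as for [iv_curve()].
#' @param Vm_grid voltage grid, V. The default spans -120 to +200 mV so
#'   the protocol covers the rising limb, the peak and the inhibited
#'   positive limb of the cycle-model I-V curve; a protocol confined to
#'   the rising limb leaves the binding constants practically
#'   non-identifiable (the fit's own condition-number warning fires).
#' @param noise_frac Gaussian noise s.d. as a fraction of `max(|I|)`.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param T temperature, K.
#' @return List of class `thz_iv_dataset` with `data` (data.frame `Vm`,
#'   `I`, `sigma_I`), `true_par`, `noise_frac`, `seed`.
#' @export
make_iv_dataset <- function(par, conc,
                            Vm_grid = seq(-0.12, 0.2, length.out = 25),
                            noise_frac = 0.05, seed = 1, T = 310) {
  stopifnot(noise_frac >= 0)
  curve <- iv_curve(par, conc, Vm_grid, T = T)
  sigma <- noise_frac * max(abs(curve$I))
  set.seed(seed)
  noise <- if (sigma > 0) rnorm(nrow(curve), 0, sigma) else 0
  structure(list(
    data = data.frame(Vm = curve$Vm, I = curve$I + noise,
                      sigma_I = rep(max(sigma, 1e-30), nrow(curve))),
    true_par = par, noise_frac = noise_frac, seed = seed
  ), class = "thz_iv_dataset")
}

#' Analytic induced transmembrane voltage of a spherical cell
#'
#' First-order closed form for the membrane voltage induced on a spherical
#' cell by a step uniform field: `1.5 E0 R cos(theta) (1 - exp(-t/tau))`
#' with the classical charging time constant
#' `tau = R C_m (1/sigma_i + 1/(2 sigma_o))` for a thin, essentially
#' insulating membrane in an unbounded medium. The membrane leak `g1`
#' shortens `tau` and shrinks the plateau by `O(g1 R / sigma)`, negligible
#' for physiological leaks. Used as the independent oracle for the
#' numerical potential/membrane solver (which carries a small, documented
#' finite-domain truncation bias).
#'
#' @param E0 applied field, V/m.
#' @param R_cell cell radius, m.
#' @param sigma_i,sigma_o medium conductivities, S/m.
#' @param C_m membrane capacitance, F/m^2.
#' @param g1 membrane leak conductance, S/m^2 (not used in the closed
#'   form; accepted for interface parity and documented as negligible).
#' @param t time(s), s.
#' @param theta polar angle(s), rad.
#' @param V_rest resting potential added to the induced component, V.
#' @return Membrane voltage, outer product shape `length(t)` x
#'   `length(theta)` (dropped to a vector when either is scalar).
#' @export
schwan_reference <- function(E0, R_cell, sigma_i, sigma_o, C_m, g1 = 0,
                             t, theta, V_rest = 0) {
  tau <- R_cell * C_m * (1 / sigma_i + 1 / (2 * sigma_o))
  out <- outer(1 - exp(-t / tau), 1.5 * E0 * R_cell * cos(theta)) + V_rest
  drop(out)
}

#' Stationary net cycle flux of the 4-state pump chain
#'
#' Independent linear-algebra oracle for [cycle_rate()]: builds the
#' 4-state Markov rate matrix with forward rates `R_i+` (state i to i+1,
#' cyclically) and backward rates `R_i-`, solves the stationary
#' distribution, and returns the net probability flux through the first
#' transition — the net turnovers per second of one pump.
#'
#' @param rates a [cycle_rates()] result (scalar components).
#' @return Net cycle flux, 1/s.
#' @export
cycle_steady_state_oracle <- function(rates) {
  kf <- c(rates$R1p[1], rates$R2p[1], rates$R3p[1], rates$R4p[1])
  kb <- c(rates$R1m[1], rates$R2m[1], rates$R3m[1], rates$R4m[1])
  Q <- matrix(0, 4, 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    Q[i, j] <- Q[i, j] + kf[i]   # i -> i+1
    Q[j, i] <- Q[j, i] + kb[i]   # i+1 -> i
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 4))
  pi_s <- tryCatch(qr.solve(A, c(0, 0, 0, 0, 1)),
                   error = function(e) stop("reducible chain: stationary ",
                                            "distribution is not unique"))
  if (any(!is.finite(pi_s))) stop("reducible chain")
  pi_s[1] * kf[1] - pi_s[2] * kb[1]
}

#' Coarse, short-horizon run configuration
#'
#' Scales the default study conditions down to a configuration whose full
#' run completes quickly: the stimulation and total horizons shrink by
#' `scale` and the stimulus-phase time step coarsens up to fourfold
#' (always still resolving each pulse). `scale = 1` reproduces the
#' full default study conditions.
#'
#' @param scale factor in (0, 1].
#' @param cell_type shipped cell type name.
#' @return List with `config` (a `thz_config`) and `plan` (a
#'   [simulation_plan()]).
#' @export
mini_config <- function(scale = 1, cell_type = "rat_neostriatal") {
  stopifnot(scale > 0, scale <= 1)
  cfg <- default_config(cell_type)
  train <- pulse_train(t_on = 1.2e-9 * scale)
  plan <- simulation_plan(
    train = train,
    t_end = 12.3e-9 * scale,
    dt_stim = pulse_width(train) / max(5, round(20 * scale)),
    n_frames = max(60, round(400 * scale)),
    experiment = sprintf("mini_scale_%g", scale)
  )
  list(config = cfg, plan = plan)
}
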