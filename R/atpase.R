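# Four-state Na+,K+-ATPase cycle model: composite forward/backward rates
# with voltage-dependent saturating ion binding, the closed-form
# steady-state cycle rate, stoichiometric ion flows (3 Na+ out : 2 K+ in
# per ATP), power dissipation, I-V curve generation and weighted
# least-squares fitting of cycle parameters to whole-cell I-V data.

# voltage-exponential clamp; must never engage below |Vm| ~ 1 V for
# physiological partition coefficients (|d| < 1 gives |arg| < ~38 at 1 V)
clamp_exp <- function(x, bound = 50) {
  if (any(abs(x) > bound)) {
    warning("voltage exponential argument clamped at |", bound, "|",
            call. = FALSE)
    x <- pmin(pmax(x, -bound), bound)
  }
  exp(x)
}

#' Composite cycle transition rates
#'
#' Evaluates the eight composite forward/backward rates of the 4-state
#' pump cycle at membrane potential `Vm` and the given ion concentrations:
#' cubic saturating binding of intracellular/extracellular Na+, quadratic
#' binding of K+, with voltage partition coefficients `d_*` splitting the
#' membrane field across the binding wells; MgATP saturation in the
#' forward E2->E1 step and in the backward phosphorylation step (which
#' also carries the `c_P * 10^(3-pH)` phosphate/proton term); MgADP
#' linearity in the backward E1P step.
#'
#' @param Vm membrane potential, V (vectorised).
#' @param c_Na_i,c_Na_o,c_K_i,c_K_o ion concentrations, mol/m^3 (scalars
#'   or vectors recycled against `Vm`).
#' @param par the `atpase` component of a [default_config()] bundle.
#' @param constants [physical_constants()].
#' @param T temperature, K.
#' @return List of class `thz_cycle_rates` with vectors `R1p`, `R2p`,
#'   `R3p`, `R4p`, `R1m`, `R2m`, `R3m`, `R4m`.
#' @export
cycle_rates <- function(Vm, c_Na_i, c_Na_o, c_K_i, c_K_o, par,
                        constants = physical_constants(T), T = 310) {
  if (any(c(c_Na_i, c_Na_o, c_K_i, c_K_o) < 0))
    stop("ion concentrations must be non-negative")
  fv <- constants$F * Vm / (constants$R_u * T)
  nai <- (c_Na_i / par$kd_Nai0) * clamp_exp(-par$d_Nai * fv)
  nao <- (c_Na_o / par$kd_Nao0) * clamp_exp(-par$d_Nao * fv)
  ki  <- (c_K_i  / par$kd_Ki0)  * clamp_exp(-par$d_Ki  * fv)
  ko  <- (c_K_o  / par$kd_Ko0)  * clamp_exp(-par$d_Ko  * fv)
  atp <- par$c_MgATP / par$kd_MgATP
  den_i <- (1 + nai)^3 + (1 + ki)^2 - 1
  den_o <- (1 + nao)^3 + (1 + ko)^2 - 1
  structure(list(
    R1p = par$k1p * nai^3 / den_i,
    R2p = rep_len(par$k2p, length(fv)),
    R3p = par$k3p * ko^2 / den_o,
    R4p = rep_len(par$k4p * atp / (1 + atp), length(fv)),
    R1m = rep_len(par$k1m * par$c_MgADP, length(fv)),
    R2m = par$k2m * nao^3 / den_o,
    R3m = rep_len(par$k3m * par$c_P * 10^(3 - par$pH) / (1 + atp),
                  length(fv)),
    R4m = par$k4m * ki^2 / den_i
  ), class = "thz_cycle_rates")
}

#' Steady-state cycle rate from the composite rates
#'
#' Closed-form net turnover rate of the 4-state cycle,
#' `(R1+ R2+ R3+ R4+ - R1- R2- R3- R4-)` over the 16-term directional-tree
#' denominator; equals the stationary net cycle flux of the corresponding
#' 4-state Markov chain (see [cycle_steady_state_oracle()]).
#'
#' @param rates a [cycle_rates()] result (vectorised component-wise).
#' @return `v_cyc`, net cycles per second (vector).
#' @export
cycle_rate <- function(rates) {
  with(rates, {
    num <- R1p * R2p * R3p * R4p - R1m * R2m * R3m * R4m
    den <- R1m * R2m * R3m + R1p * R2m * R3m + R1p * R2p * R3m +
      R1p * R2p * R3p +
      R2m * R3m * R4m + R2p * R3m * R4m + R2p * R3p * R4m +
      R2p * R3p * R4p +
      R1m * R3m * R4m + R1m * R3p * R4m + R1m * R3p * R4p +
      R1p * R3p * R4p +
      R1m * R2m * R4m + R1m * R2m * R4p + R1p * R2m * R4p +
      R1p * R2p * R4p
    if (any(den == 0))
      stop("degenerate cycle parameterization: denominator is zero")
    num / den
  })
}

#' Whole-cell pump current
#'
#' `I = F_c * v_cyc`, with `F_c` the lumped current scale (ampere-seconds
#' per cycle) absorbing membrane capacitance and pump surface density.
#'
#' @param v_cyc cycle rate, 1/s.
#' @param F_c current scale factor, A s.
#' @return Current, A.
#' @export
pump_current <- function(v_cyc, F_c) F_c * v_cyc

#' Per-angle pump ion flows from the whole-cell current
#'
#' Splits the whole-cell stoichiometric flows `J_Na = 3 I / q_ele / N_A`
#' and `J_K = -2 I / q_ele / N_A` (mol/s; positive = out of the cell)
#' across the theta elements in proportion to their membrane area.
#'
#' @param I whole-cell pump current, A.
#' @param A_theta element areas, m^2 (must sum to `A_cell`).
#' @param A_cell whole-cell membrane area, m^2.
#' @param constants [physical_constants()].
#' @return List with per-theta `J_Na`, `J_K` (mol/s) and whole-cell
#'   `J_Na_total`, `J_K_total`.
#' @export
pump_flows_theta <- function(I, A_theta, A_cell,
                             constants = physical_constants()) {
  stopifnot(abs(sum(A_theta) - A_cell) < 1e-9 * A_cell)
  base <- I / constants$q_ele / constants$N_A
  list(J_Na = 3 * base / A_cell * A_theta,
       J_K = -2 * base / A_cell * A_theta,
       J_Na_total = 3 * base, J_K_total = -2 * base)
}

#' Pump power dissipation
#'
#' ATP hydrolysis power of the pump. `mode = "literal"` evaluates the
#' printed form `Q_ATP * I / q_ele / N_A`; `mode = "per_molecule"`
#' evaluates `Q_ATP * I / q_ele`, which (with `Q_ATP` an energy per
#' molecule and `I/q_ele` the ATP consumption rate in molecules per
#' second) is the dimensionally consistent wattage and the mode the
#' simulator records. The two differ by exactly the Avogadro constant.
#'
#' @param I pump current, A.
#' @param constants [physical_constants()].
#' @param mode `"literal"` or `"per_molecule"`.
#' @return Power, W.
#' @export
pump_power <- function(I, constants = physical_constants(),
                       mode = c("literal", "per_molecule")) {
  mode <- match.arg(mode)
  p <- constants$Q_ATP * I / constants$q_ele
  if (mode == "literal") p / constants$N_A else p
}

#' Pump current-voltage curve
#'
#' Whole-cell pump current over a membrane-potential grid at fixed ion
#' concentrations (defaulting to the initial whole-cell concentrations of
#' the bundle's species table).
#'
#' @param par `atpase` parameter list.
#' @param conc named list/vector with `c_Na_i`, `c_Na_o`, `c_K_i`,
#'   `c_K_o` (mol/m^3).
#' @param Vm_grid membrane potentials, V.
#' @param constants [physical_constants()].
#' @param T temperature, K.
#' @return `data.frame(Vm, I)`.
#' @export
iv_curve <- function(par, conc, Vm_grid = seq(-0.12, 0.06, by = 0.002),
                     constants = physical_constants(T), T = 310) {
  stopifnot(all(is.finite(Vm_grid)))
  r <- cycle_rates(Vm_grid, conc$c_Na_i, conc$c_Na_o, conc$c_K_i,
                   conc$c_K_o, par, constants, T)
  data.frame(Vm = Vm_grid, I = pump_current(cycle_rate(r), par$F_c))
}

#' Initial whole-cell concentrations of a bundle
#'
#' @param cfg a `thz_config` bundle.
#' @return List with `c_Na_i`, `c_Na_o`, `c_K_i`, `c_K_o`.
#' @export
initial_concentrations <- function(cfg) {
  list(c_Na_i = cfg$species$Na$c_i0, c_Na_o = cfg$species$Na$c_o0,
       c_K_i = cfg$species$K$c_i0, c_K_o = cfg$species$K$c_o0)
}

#' Fit cycle parameters to whole-cell I-V data
#'
#' Weighted least squares (Levenberg-Marquardt, multi-start) of
#' [iv_curve()] against measured `(Vm, I)` points. Only the parameters
#' named in `free` are varied; positivity-constrained parameters are kept
#' positive through box constraints. The cycle model is strongly
#' parameter-degenerate, so the fit is seeded multi-start and a
#' practical-identifiability warning is emitted when the scaled
#' Jacobian cross-product is near singular.
#'
#' @param data data.frame with columns `Vm` (V), `I` (A) and optionally
#'   `sigma_I` (A, per-point uncertainty; defaults to equal weights).
#' @param par_init full `atpase` parameter list used as the initial guess
#'   and as the fixed values of non-free parameters.
#' @param conc concentrations as for [iv_curve()].
#' @param free character vector of free parameter names (possibly empty).
#' @param n_starts number of seeded multi-start perturbations.
#' @param seed RNG seed for the multi-start perturbations.
#' @param constants [physical_constants()].
#' @param T temperature, K.
#' @return List with `par` (full updated parameter list), `estimate`,
#'   `se` (named vectors over the free parameters), `residuals`,
#'   `converged`, `deviance`, `condition`, `identifiability_warning`.
#' @export
fit_iv <- function(data, par_init, conc, free, n_starts = 5, seed = 1,
                   constants = physical_constants(T), T = 310) {
  stopifnot(all(c("Vm", "I") %in% names(data)))
  sigma <- if ("sigma_I" %in% names(data)) data$sigma_I
           else rep(1, nrow(data))
  if (length(free) == 0) {
    res <- (data$I - iv_curve(par_init, conc, data$Vm, constants, T)$I) /
      sigma
    return(list(par = par_init, estimate = numeric(0), se = numeric(0),
                residuals = res, converged = TRUE,
                deviance = sum(res^2), condition = NA_real_,
                identifiability_warning = FALSE))
  }
  if (nrow(data) < length(free))
    stop("need at least as many data points as free parameters")
  bad <- setdiff(free, names(par_init))
  if (length(bad)) stop("unknown free parameters: ",
                        paste(bad, collapse = ", "))
  positive <- !grepl("^d_", free)  # partition coefficients may be signed

  resid_fn <- function(p) {
    par <- par_init
    par[free] <- as.list(p)
    (data$I - iv_curve(par, conc, data$Vm, constants, T)$I) / sigma
  }
  p0 <- unlist(par_init[free])
  lower <- ifelse(positive, pmax(p0 * 1e-4, 1e-300), -Inf)
  upper <- ifelse(positive, p0 * 1e4, Inf)

  set.seed(seed)
  starts <- c(list(p0), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
    pmin(pmax(p0 * exp(rnorm(length(p0), 0, 0.3)), lower), upper)
  }))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("I-V fit failed to converge from any start")

  sm <- summary(best)
  se <- setNames(sm$coefficients[, "Std. Error"], free)
  est <- setNames(best$par, free)
  hess <- best$hessian
  cond <- tryCatch(kappa(hess, exact = TRUE), error = function(e) Inf)
  ident <- !is.finite(cond) || cond > 1e10
  if (ident)
    warning("near-singular fit: parameters are practically ",
            "non-identifiable from these data", call. = FALSE)
  par_out <- par_init
  par_out[free] <- as.list(unname(est))
  list(par = par_out, estimate = est, se = se,
       residuals = best$fvec, converged = best$info %in% 1:4,
       deviance = best$deviance, condition = cond,
       identifiability_warning = ident)
}
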