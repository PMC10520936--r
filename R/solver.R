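# Quasi-static potential solve on the axisymmetric spherical cell and the
# per-theta membrane charging equation.
#
# The bulk media are uniform ohmic conductors, so at each instant the
# potential obeys Laplace's equation in both regions with (i) a prescribed
# jump Phi_i - Phi_o = Vm(theta) across the (thin) membrane, (ii)
# continuity of normal conduction current across it, and (iii) a Dirichlet
# uniform-field condition Phi = -E(t) r cos(theta) on the outer boundary.
# Each Legendre mode l decouples into a 3x3 linear system for the radial
# coefficients, so the map (Vm, E) -> normal membrane current density is
# linear and is precomputed once as J_n = M %*% Vm + w * E.

legendre_p <- function(l, x) {
  # Legendre polynomial P_l at x (vectorised); pracma::legendre returns the
  # associated functions P_l^m for m = 0..l, row 1 is m = 0.
  if (l == 0) return(rep(1, length(x)))
  matrix(pracma::legendre(l, x), nrow = l + 1)[1, ]
}

#' Polar-angle grid of the membrane
#'
#' Uniform grid in theta over \[0, pi\] with `N_theta` nodes; the default
#' `N_theta = 13` makes the seven reportable angles 0, pi/6, ..., pi grid
#' nodes. Also returns the membrane element areas `A_theta` (conical bands
#' centred on each node, summing exactly to the cell area) and the matching
#' intracellular / extracellular sector volumes used by the concentration
#' bookkeeping.
#'
#' @param geometry the `geometry` component of a [default_config()] bundle.
#' @return List with `theta`, `u = cos(theta)`, `A_theta`, `A_cell`,
#'   `V_in`, `V_out`.
#' @export
theta_grid <- function(geometry) {
  K <- geometry$N_theta
  R <- geometry$R_cell
  Rd <- geometry$R_domain
  theta <- seq(0, pi, length.out = K)
  edges <- c(0, (theta[-K] + theta[-1]) / 2, pi)
  dcos <- cos(edges[-(K + 1)]) - cos(edges[-1])  # positive, sums to 2
  A_theta <- 2 * pi * R^2 * dcos
  V_in <- (2 * pi / 3) * R^3 * dcos
  V_out <- (2 * pi / 3) * (Rd^3 - R^3) * dcos
  list(theta = theta, u = cos(theta), A_theta = A_theta,
       A_cell = 4 * pi * R^2, V_in = V_in, V_out = V_out)
}

#' Precompute the linear potential-solve operator
#'
#' Solves the per-mode 3x3 systems once and assembles the matrix `M` and
#' vector `w` such that the normal conduction current density at the
#' membrane (positive outward, A/m^2, evaluated at the theta nodes) is
#' `J_n = M %*% Vm + w * E` for any membrane potential profile `Vm` and
#' applied uniform field `E`. Also stores the radial coefficient maps used
#' by [solve_potential()] to reconstruct the full fields, and the explicit
#' stability bound `dt_stable` for the membrane charging update.
#'
#' @param geometry,electrical components of a [default_config()] bundle.
#' @return A list of class `thz_field_operator`.
#' @export
field_operator <- function(geometry, electrical) {
  g <- theta_grid(geometry)
  K <- geometry$N_theta
  R <- geometry$R_cell
  Rd <- geometry$R_domain
  si <- electrical$sigma_i
  so <- electrical$sigma_o
  L <- K - 1
  rho <- Rd / R

  P <- sapply(0:L, function(l) legendre_p(l, g$u))   # K x (L+1)
  Pinv <- solve(P)

  # per-mode coefficient maps: interior A (r/R)^l; exterior
  # C (r/Rd)^l + D (R/r)^(l+1) — the growing branch is normalised at the
  # outer boundary and the decaying branch at the membrane, which keeps
  # every matrix entry O(1) at arbitrary mode order.
  coefV <- matrix(0, 3, L + 1)  # response to unit V_l
  coefE <- matrix(0, 3, L + 1)  # response to unit applied field E
  for (l in 0:L) {
    Amat <- rbind(
      c(1, -rho^-l, -1),                           # jump at r = R
      c(si * l, -so * l * rho^-l, so * (l + 1)),   # current continuity
      c(0, 1, rho^-(l + 1))                        # outer Dirichlet
    )
    coefV[, l + 1] <- solve(Amat, c(1, 0, 0))
    if (l == 1) coefE[, l + 1] <- solve(Amat, c(0, 0, -Rd))
  }

  # J_n = -sigma_i dPhi_i/dr at R = -sigma_i * A_l * l / R per mode
  dV <- -si * (0:L) / R * coefV[1, ]
  dE <- -si * (0:L) / R * coefE[1, ]
  M <- P %*% (dV * Pinv)        # row-scale Pinv by dV
  w <- as.numeric(P %*% dE)

  g_max <- max(abs(dV))         # worst per-mode conductance, S/m^2
  structure(list(grid = g, P = P, Pinv = Pinv, coefV = coefV,
                 coefE = coefE, M = M, w = w, R = R, Rd = Rd,
                 sigma_i = si, sigma_o = so, L = L,
                 g_max = g_max,
                 dt_stable = electrical$C_m / (g_max + electrical$g1)),
            class = "thz_field_operator")
}

#' Solve the quasi-static potential for a given membrane state
#'
#' Reconstructs the intracellular and extracellular potential fields and
#' the normal membrane current densities for a membrane potential profile
#' `Vm` (on the theta nodes) under applied uniform field `E_applied`. The
#' returned fields satisfy Laplace's equation (exactly, mode by mode), the
#' prescribed jump `Phi_i - Phi_o = Vm` at the membrane nodes, and the
#' outer-boundary condition `Phi = -E r cos(theta)`.
#'
#' @param op a [field_operator()].
#' @param Vm membrane potential per theta node, V.
#' @param E_applied applied uniform field, V/m.
#' @param geometry geometry component (for the radial node counts).
#' @return List with `r_in`, `r_out`, `theta`, matrices `Phi_in`
#'   (`N_r_in` x `N_theta`), `Phi_out`, and `J_n` (normal conduction
#'   current density at the membrane per theta, positive outward, equal on
#'   both faces by construction).
#' @export
solve_potential <- function(op, Vm, E_applied, geometry) {
  stopifnot(length(Vm) == nrow(op$P), is.finite(E_applied))
  coef <- as.numeric(op$Pinv %*% Vm)
  A <- op$coefV[1, ] * coef + op$coefE[1, ] * E_applied
  C <- op$coefV[2, ] * coef + op$coefE[2, ] * E_applied
  D <- op$coefV[3, ] * coef + op$coefE[3, ] * E_applied

  r_in <- seq(op$R / geometry$N_r_in, op$R, length.out = geometry$N_r_in)
  r_out <- seq(op$R, op$Rd, length.out = geometry$N_r_out)
  L <- op$L
  Phi_in <- outer(r_in, 0:L, function(r, l) (r / op$R)^l) %*%
    (A * t(op$P)) # (N_r x L+1) %*% (L+1 x K)
  Phi_out <- (outer(r_out, 0:L, function(r, l) (r / op$Rd)^l) %*%
                (C * t(op$P))) +
             (outer(r_out, 0:L, function(r, l) (op$R / r)^(l + 1)) %*%
                (D * t(op$P)))
  J_n <- as.numeric(op$M %*% Vm + op$w * E_applied)
  list(r_in = r_in, r_out = r_out, theta = op$grid$theta,
       Phi_in = Phi_in, Phi_out = Phi_out, J_n = J_n)
}

#' Advance the membrane potential by current continuity
#'
#' One explicit Euler step of the per-theta membrane charging equation
#' `C_m dVm/dt = J_n - g1 (Vm - V_rest) - I_p`, where `J_n` is the bulk
#' conduction current density arriving at the membrane and `I_p` the pore
#' current density.
#'
#' @param Vm membrane potential per theta, V.
#' @param J_n conduction current density per theta (from the potential
#'   solve), A/m^2.
#' @param I_p pore current density per theta, A/m^2.
#' @param electrical electrical component of the bundle.
#' @param dt time step, s.
#' @param dt_max optional explicit stability bound (from
#'   `field_operator()$dt_stable`, possibly tightened by the pore
#'   conductance); exceeding it raises an error advising a smaller step.
#' @return Updated `Vm`.
#' @export
step_membrane_potential <- function(Vm, J_n, I_p, electrical, dt,
                                    dt_max = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(J_n)) || !all(is.finite(I_p)))
    stop("non-finite current density passed to membrane update")
  if (!is.null(dt_max) && dt > dt_max) {
    stop(sprintf(paste0("explicit stability bound exceeded: dt = %.3g s ",
                        "> %.3g s; reduce the time step"), dt, dt_max))
  }
  Vm + dt / electrical$C_m *
    (J_n - electrical$g1 * (Vm - electrical$V_rest) - I_p)
}

#' Effective membrane conductivity diagnostic
#'
#' Per-theta effective conductivity `I_p / Vm` (S/m^2) where `|Vm|` exceeds
#' a floor voltage; below the floor the linearised pore-geometry estimate
#' `g_geom` is used instead, and the result is zero wherever there is no
#' open pore area.
#'
#' @param I_p pore current density per theta, A/m^2.
#' @param Vm membrane potential per theta, V.
#' @param g_geom linearised pore conductance estimate per theta, S/m^2
#'   (see [pore_conductance_estimate()]); zero when no pores exist.
#' @param v_floor floor voltage, V.
#' @return Per-theta conductivity, S/m^2.
#' @export
membrane_conductivity <- function(I_p, Vm, g_geom = 0, v_floor = 1e-3) {
  g_geom <- rep_len(g_geom, length(Vm))
  ifelse(abs(Vm) > v_floor, I_p / Vm, g_geom)
}
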