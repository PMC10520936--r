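# Transmembrane ion fluxes through open pore area: generalized modified
# Poisson-Nernst-Planck (drift + diffusion + finite-ion-size steric term),
# discretised as two-point differences across the membrane thickness, and
# the conical-sector concentration bookkeeping.

species_vectors <- function(species) {
  list(name = names(species),
       z = vapply(species, `[[`, numeric(1), "z"),
       D = vapply(species, `[[`, numeric(1), "D"),
       a = vapply(species, `[[`, numeric(1), "a"))
}

#' Transmembrane flux density through unit pore area (GMPNP)
#'
#' Evaluates, per species and theta node, the generalized modified
#' Poisson-Nernst-Planck flux
#' `J_j = -D_j c_j F z_j/(R_u T) grad(Phi) - D_j grad(c_j)
#'        - D_j c_j (sum_k N_A a_k^3 grad(c_k)) / (1 - sum_k N_A a_k^3 c_k)`
#' with outward-normal two-point differences over the membrane thickness:
#' `grad(Phi) = -Vm/d_mem`, `grad(c_j) = (c_o,j - c_i,j)/d_mem`, and `c_j`
#' the arithmetic mid-membrane mean. Positive flux is cell-to-exterior.
#' With all effective radii zero the expression reduces exactly to
#' classical Nernst-Planck drift-diffusion.
#'
#' @param species species list (from the bundle).
#' @param c_i,c_o intracellular/extracellular concentrations, mol/m^3:
#'   either length-4 vectors (one theta) or 4 x K matrices.
#' @param Vm membrane potential, V (scalar or length K).
#' @param d_mem membrane thickness, m.
#' @param T temperature, K.
#' @param constants [physical_constants()].
#' @return Flux per unit pore area, mol/(m^2 s), same shape as `c_i`.
#' @export
gmpnp_flux_density <- function(species, c_i, c_o, Vm, d_mem, T,
                               constants = physical_constants(T)) {
  sv <- species_vectors(species)
  mat <- is.matrix(c_i)
  c_i <- rbind(c_i); c_o <- rbind(c_o)
  if (!mat) { c_i <- matrix(c_i, ncol = 1); c_o <- matrix(c_o, ncol = 1) }
  ns <- nrow(c_i)
  K <- ncol(c_i)
  a3 <- constants$N_A * sv$a^3
  cbar <- (c_i + c_o) / 2
  occ_i <- colSums(a3 * c_i); occ_o <- colSums(a3 * c_o)
  if (any(occ_i >= 1) || any(occ_o >= 1))
    stop("steric occupancy reached 1: the modified PNP model is invalid ",
         "at these concentrations")
  occ <- colSums(a3 * cbar)
  gradc <- (c_o - c_i) / d_mem
  gradphi <- matrix(rep(-Vm / d_mem, each = ns), ns, K)
  drift <- -(sv$D * cbar) * (constants$F * sv$z / (constants$R_u * T)) *
    gradphi
  diffu <- -sv$D * gradc
  steric <- -(sv$D * cbar) *
    matrix(rep(colSums(a3 * gradc) / (1 - occ), each = ns), ns, K)
  J <- drift + diffu + steric
  rownames(J) <- sv$name
  if (!mat) J <- J[, 1]
  J
}

#' Scale pore-area flux densities to membrane-element fluxes and current
#'
#' Multiplies per-species flux densities (per unit pore area) by the
#' fractional open area `f_p(theta)` and forms the pore current density
#' from the exact charge-flux identity `I_p = F sum_j z_j J_j`.
#'
#' @param J_dens per-species flux density, 4 x K (or length-4 vector).
#' @param f_p fractional open pore area per theta (length K or scalar).
#' @param species species list.
#' @param constants [physical_constants()].
#' @return List with `J_pore` (same shape as `J_dens`, mol/(m^2 s) of
#'   membrane area) and `I_p` (per-theta current density, A/m^2).
#' @export
pore_flux <- function(J_dens, f_p, species, constants = physical_constants()) {
  if (any(f_p > 1)) stop("fractional open pore area exceeds 1")
  sv <- species_vectors(species)
  vec <- !is.matrix(J_dens)
  J <- rbind(J_dens)
  if (vec) J <- matrix(J_dens, ncol = 1)
  J_pore <- J * matrix(rep(f_p, each = nrow(J)), nrow(J), ncol(J))
  I_p <- constants$F * colSums(sv$z * J_pore)
  rownames(J_pore) <- sv$name
  if (vec) J_pore <- J_pore[, 1]
  list(J_pore = J_pore, I_p = I_p)
}

#' Linearised pore conductance estimate
#'
#' Small-signal membrane conductance of the open pore area from the drift
#' term alone, `g = f_p F^2 / (R_u T d_mem) sum_j z_j^2 D_j c_j`; used as
#' the below-floor fallback of [membrane_conductivity()]. Zero wherever
#' `f_p` is zero.
#'
#' @param species species list.
#' @param c_i,c_o concentrations, 4 x K.
#' @param f_p fractional open area per theta.
#' @param d_mem membrane thickness, m.
#' @param T temperature, K.
#' @param constants [physical_constants()].
#' @return Per-theta conductance, S/m^2.
#' @export
pore_conductance_estimate <- function(species, c_i, c_o, f_p, d_mem, T,
                                      constants = physical_constants(T)) {
  sv <- species_vectors(species)
  cbar <- (rbind(c_i) + rbind(c_o)) / 2
  f_p * constants$F^2 / (constants$R_u * T * d_mem) *
    colSums(sv$z^2 * sv$D * cbar)
}

#' Advance compartment concentrations by explicit flux bookkeeping
#'
#' Each theta node owns a conical intracellular sector of volume
#' `V_in[k]` and (in the default finite-bath mode) a matching
#' extracellular shell sector `V_out[k]`. An outward flux `J` (mol/(m^2 s)
#' of membrane area) moves `J * A_theta * dt` moles from the inside to the
#' outside, so total moles per species are conserved to round-off. In
#' `bath = "infinite"` mode the extracellular side is clamped.
#'
#' @param c_i,c_o concentrations, 4 x K matrices.
#' @param J total outward flux per species/theta (pores + pump), 4 x K.
#' @param grid a [theta_grid()].
#' @param dt time step, s.
#' @param bath `"finite"` (default) or `"infinite"`.
#' @param negative `"error"` (default), `"limit"` (donor-limited: no
#'   compartment can export more moles than it holds, exactly
#'   mass-conserving) or `"clamp"` (clamp at zero with a warning; mass
#'   balance degraded). The simulator handles its configured sub-stepping
#'   by redoing whole physics steps at smaller dt and falls back to
#'   `"limit"` when halving cannot cure the sign (a drained compartment
#'   under sustained outward drift).
#' @return List with updated `c_i`, `c_o`.
#' @export
update_concentrations <- function(c_i, c_o, J, grid, dt,
                                  bath = c("finite", "infinite"),
                                  negative = c("error", "limit",
                                               "clamp")) {
  bath <- match.arg(bath); negative <- match.arg(negative)
  if (dt <= 0) stop("dt must be positive")
  ns <- nrow(c_i)
  Ath <- matrix(rep(grid$A_theta, each = ns), ns)
  Vin <- matrix(rep(grid$V_in, each = ns), ns)
  Vout <- matrix(rep(grid$V_out, each = ns), ns)
  moles <- J * Ath * dt
  if (negative == "limit") {
    moles <- pmin(moles, c_i * Vin)                 # export <= interior content
    if (bath == "finite") moles <- pmax(moles, -c_o * Vout)
  }
  ci_new <- c_i - moles / Vin
  co_new <- if (bath == "finite") c_o + moles / Vout else c_o
  if (negative == "limit") {
    # the limited transfer can leave an O(machine-eps) negative residue
    ci_new <- pmax(ci_new, 0)
    co_new <- pmax(co_new, 0)
  }
  if (any(ci_new < 0) || any(co_new < 0)) {
    if (negative %in% c("error", "limit")) {
      stop("concentration update would go negative; reduce dt")
    }
    warning("concentrations clamped at zero; mass balance degraded",
            call. = FALSE)
    ci_new <- pmax(ci_new, 0)
    co_new <- pmax(co_new, 0)
  }
  list(c_i = ci_new, c_o = co_new)
}

#' Unweighted polar-angle average
#'
#' Plain arithmetic mean over the theta nodes (NOT area/sin-theta
#' weighted) -- the averaging convention used for all whole-cell "average"
#' series. Accepts a vector (one instant) or a time-by-theta matrix.
#'
#' @param x per-theta vector or (time x theta) matrix.
#' @return Scalar or per-time vector of unweighted means.
#' @export
average_unweighted <- function(x) {
  if (is.matrix(x)) rowMeans(x) else mean(x)
}
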