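# Asymptotic hydrophilic-pore model: density ODE, per-pore radius dynamics
# and pore-area-coupled effective membrane tension.
#
# Pores are tracked deterministically as per-theta "cohorts" (radius,
# count): the density ODE is the source of truth for how many pores exist,
# and positive density increments spawn cohorts at the minimum radius
# r_star, which then evolve by the radius ODE under the whole-cell
# effective tension. Because all cohorts at one theta obey the same
# first-order radius ODE their radii never cross, so each cohort column
# stays ordered by birth and nearest-radius merging is a cheap adjacent
# operation.

q_p_of <- function(pore) (pore$r_m / pore$r_star)^pore$q_exp

# squared normalised voltage with the documented overflow cap
vep_u <- function(Vm, pore) {
  u <- (Vm / pore$V_ep)^2
  cap <- pore$vep_ratio_cap %||% 250
  if (any(u > cap)) {
    warning("(Vm/V_ep)^2 capped at ", cap, " to avoid overflow",
            call. = FALSE)
    u <- pmin(u, cap)
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equilibrium hydrophilic-pore density
#'
#' `N_eq(Vm) = N0 exp(q_p (Vm/V_ep)^2)` with `q_p = (r_m/r_star)^q_exp`.
#' Even in `Vm` and monotone increasing in `|Vm|`. The squared voltage
#' ratio is capped (with a warning) at `pore$vep_ratio_cap` to guard
#' against overflow at extreme excursions.
#'
#' @param Vm membrane potential, V (vectorised).
#' @param pore the `pore` component of a [default_config()] bundle.
#' @return Pore density, 1/m^2.
#' @export
equilibrium_density <- function(Vm, pore) {
  pore$N0 * exp(pmin(q_p_of(pore) * vep_u(Vm, pore), 700))
}

#' Pore density creation/resealing rate
#'
#' `dN/dt = alpha exp((Vm/V_ep)^2) (1 - N / N_eq(Vm))`: positive below the
#' equilibrium density, zero at it, negative (resealing) above it.
#'
#' @param N current pore density, 1/m^2.
#' @param Vm membrane potential, V.
#' @param pore pore parameter list.
#' @return `dN/dt`, 1/(m^2 s).
#' @export
density_rate <- function(N, Vm, pore) {
  if (any(N < 0)) stop("pore density must be non-negative")
  pore$alpha * exp(vep_u(Vm, pore)) * (1 - N / equilibrium_density(Vm, pore))
}

#' Effective membrane tension under pore-area coupling
#'
#' `sigma_eff = 2 sigma' - (2 sigma' - sigma_0) / (1 - A_p/A_cell)^2`:
#' equals `sigma_0` at zero pore area and decreases strictly as the total
#' pore area grows, the negative feedback that arrests pore expansion.
#'
#' @param A_p total pore area over the whole cell, m^2.
#' @param A_cell membrane area, m^2.
#' @param pore pore parameter list.
#' @return Tension, N/m.
#' @export
effective_tension <- function(A_p, A_cell, pore) {
  if (any(A_p < 0)) stop("pore area must be non-negative")
  if (any(A_p >= A_cell))
    stop("total pore area reached the whole-cell area: tension model ",
         "leaves its validity range")
  2 * pore$sigma_prime -
    (2 * pore$sigma_prime - pore$sigma_0) / (1 - A_p / A_cell)^2
}

#' Pore radius growth rate
#'
#' `dr/dt = (D_p / k_B T) [ Vm^2 F_max / (1 + r_h/(r + r_t))
#'   + 4 beta (r_star/r)^4 / r - 2 pi gamma + 2 pi sigma_eff r ]`:
#' electrical expansion force, steric repulsion of the pore walls, edge
#' (line tension) contraction, and surface-tension expansion.
#'
#' @param r pore radius, m (vector or matrix); must be `>= r_star`.
#' @param Vm membrane potential, V (recycled against `r`).
#' @param sigma_eff effective tension, N/m.
#' @param pore pore parameter list.
#' @param T absolute temperature, K.
#' @param k_B Boltzmann constant, J/K.
#' @return `dr/dt`, m/s, same shape as `r`.
#' @export
radius_rate <- function(r, Vm, sigma_eff, pore, T, k_B = 1.380649e-23) {
  if (any(r < pore$r_star * (1 - 1e-12)))
    stop("pore radius below the minimum radius r_star")
  force <- Vm^2 * pore$F_max / (1 + pore$r_h / (r + pore$r_t)) +
    4 * pore$beta * (pore$r_star / r)^4 / r -
    2 * pi * pore$gamma +
    2 * pi * sigma_eff * r
  pore$D_p / (k_B * T) * force
}

#' Equilibrium pore radius at zero voltage
#'
#' Bracketed root of [radius_rate()] at `Vm = 0` and `sigma_eff =
#' sigma_0`; used to seed the resting pore population.
#'
#' @param pore pore parameter list.
#' @param T temperature, K.
#' @return Radius, m.
#' @export
equilibrium_radius <- function(pore, T = 310) {
  f <- function(r) radius_rate(r, 0, pore$sigma_0, pore, T)
  uniroot(f, c(pore$r_star * 1.0001, 50e-9), tol = 1e-15)$root
}

#' Initialise the pore state
#'
#' Pore density starts at the zero-voltage equilibrium `N0` on every theta
#' node. With `resting_cohorts = TRUE` (the default used by the
#' simulator), the corresponding resting pores are represented by one
#' cohort per theta at the zero-voltage equilibrium radius; their open
#' area is vanishingly small but nonzero. With `FALSE` the cohort table
#' starts empty (no open pore area at all).
#'
#' @param grid a [theta_grid()].
#' @param pore pore parameter list.
#' @param options options component of the bundle (cohort cap etc.).
#' @param T temperature, K.
#' @param resting_cohorts seed resting pores as cohorts?
#' @return A list of class `thz_pore_state` with per-theta density `N`,
#'   pending spawn counts, cohort radius/count matrices (`cap` rows), slot
#'   fill counts, and the running total pore area `A_p`.
#' @export
pore_state_init <- function(grid, pore, options = list(), T = 310,
                            resting_cohorts = TRUE) {
  K <- length(grid$theta)
  cap <- options$cohort_cap %||% 64
  r <- matrix(pore$r_star, cap, K)
  cnt <- matrix(0, cap, K)
  nfill <- integer(K)
  if (resting_cohorts) {
    r_eq <- equilibrium_radius(pore, T)
    r[1, ] <- r_eq
    cnt[1, ] <- pore$N0 * grid$A_theta
    nfill[] <- 1L
  }
  st <- list(N = rep(pore$N0, K), pending = numeric(K),
             r = r, cnt = cnt, nfill = nfill,
             A_theta = grid$A_theta, A_cell = grid$A_cell,
             A_p_theta = pi * colSums(cnt * r^2),
             cap = cap,
             spawn_min = options$spawn_min %||% 1e-3,
             merge_tol = options$merge_tol %||% 1e-3)
  st$A_p <- sum(st$A_p_theta)
  class(st) <- "thz_pore_state"
  st
}

#' @export
print.thz_pore_state <- function(x, ...) {
  cat(sprintf("<thz_pore_state> %d theta nodes, %d cohorts, N in [%.3g, %.3g] /m^2, A_p/A_cell = %.3g\n",
              length(x$N), sum(x$nfill), min(x$N), max(x$N),
              x$A_p / x$A_cell))
  invisible(x)
}

# merge cohort rows i and i+1 of column k, preserving count and open area
merge_rows <- function(st, k, i) {
  n <- st$nfill[k]
  c1 <- st$cnt[i, k]; c2 <- st$cnt[i + 1, k]
  rnew <- sqrt((c1 * st$r[i, k]^2 + c2 * st$r[i + 1, k]^2) /
                 max(c1 + c2, .Machine$double.xmin))
  st$cnt[i, k] <- c1 + c2
  st$r[i, k] <- rnew
  if (i + 1 < n) {
    idx <- (i + 1):(n - 1)
    st$r[idx, k] <- st$r[idx + 1, k]
    st$cnt[idx, k] <- st$cnt[idx + 1, k]
  }
  st$cnt[n, k] <- 0
  st$r[n, k] <- NA_real_
  st$nfill[k] <- n - 1L
  st
}

#' Advance the pore subsystem by one time step
#'
#' Performs, in order: (i) exact exponential update of the per-theta pore
#' density toward `N_eq(Vm)` (exact for `Vm` frozen over the step, hence
#' unconditionally stable through the activation burst); (ii) uniform
#' down-scaling of cohort counts when the density reseals; (iii)
#' accumulation of positive density increments into per-theta pending
#' counts, spawning a new cohort at `r_star` once the pending count
#' exceeds `spawn_min` pores (newborn cohorts within `merge_tol` relative
#' radius of the youngest cohort merge into it, and the nearest-radius
#' adjacent pair is merged whenever the cohort cap is hit); (iv) explicit
#' Euler advance of every cohort radius under the current whole-cell
#' effective tension, clamped at `r_star`; (v) recomputation of the total
#' pore area. The update depends on `Vm` only through `Vm^2`, so the
#' subsystem is exactly even in the membrane potential.
#'
#' @param st a `thz_pore_state`.
#' @param Vm membrane potential per theta, V.
#' @param dt time step, s.
#' @param pore pore parameter list.
#' @param T temperature, K.
#' @return Updated state.
#' @export
step_pores <- function(st, Vm, dt, pore, T = 310) {
  if (dt <= 0) stop("dt must be positive")
  u <- vep_u(Vm, pore)
  Neq <- pore$N0 * exp(pmin(q_p_of(pore) * u, 700))
  a <- pore$alpha * exp(u)
  # expm1 form: immune to the huge-Neq cancellation and exact in both the
  # stiff (relax-to-Neq) and slow (Euler-increment) regimes
  Nnew <- st$N - (Neq - st$N) * expm1(-a * dt / Neq)
  dN <- Nnew - st$N

  shrink <- which(dN < 0 & st$N > 0)
  if (length(shrink)) {
    f <- Nnew[shrink] / st$N[shrink]
    st$cnt[, shrink] <- st$cnt[, shrink, drop = FALSE] *
      rep(f, each = st$cap)
    st$pending[shrink] <- st$pending[shrink] * f
  }
  grow <- dN > 0
  if (any(grow)) {
    st$pending[grow] <- st$pending[grow] + dN[grow] * st$A_theta[grow]
  }
  st$N <- Nnew

  for (k in which(st$pending > st$spawn_min)) {
    n <- st$nfill[k]
    if (n > 0 &&
        abs(st$r[n, k] - pore$r_star) < st$merge_tol * pore$r_star) {
      # youngest cohort is still at birth radius: absorb into it
      c1 <- st$cnt[n, k]; c2 <- st$pending[k]
      st$r[n, k] <- sqrt((c1 * st$r[n, k]^2 + c2 * pore$r_star^2) /
                           (c1 + c2))
      st$cnt[n, k] <- c1 + c2
    } else {
      if (n >= st$cap) {
        i <- which.min(abs(diff(st$r[1:n, k])))
        st <- merge_rows(st, k, i)
        n <- st$nfill[k]
      }
      st$r[n + 1, k] <- pore$r_star
      st$cnt[n + 1, k] <- st$pending[k]
      st$nfill[k] <- n + 1L
    }
    st$pending[k] <- 0
  }

  live <- st$cnt > 0
  if (any(live)) {
    sig <- effective_tension(st$A_p, st$A_cell, pore)
    Vm2 <- rep(Vm, each = st$cap)
    rr <- st$r
    rr[!live] <- pore$r_star  # placeholder radii take no part
    drdt <- radius_rate(rr, sqrt(Vm2^2), sig, pore, T)
    rr <- pmax(rr + dt * drdt, pore$r_star)
    st$r[live] <- rr[live]
  }

  st$A_p_theta <- pi * colSums(st$cnt * ifelse(is.na(st$r), 0, st$r)^2)
  st$A_p <- sum(st$A_p_theta)
  if (st$A_p >= st$A_cell) {
    stop("total pore area reached the cell area during a pore step; ",
         "simulation state is unphysical (reduce dt or the field)")
  }
  st
}

#' Summaries of a pore state
#'
#' @param st a `thz_pore_state`.
#' @return List with per-theta pore count, mean radius (count-weighted, NA
#'   where no pores), open-area fraction `f_p`, and totals.
#' @export
pore_summary <- function(st) {
  count <- colSums(st$cnt)
  wr <- colSums(st$cnt * ifelse(is.na(st$r), 0, st$r))
  list(count = count,
       mean_radius = ifelse(count > 0, wr / count, NA_real_),
       f_p = st$A_p_theta / st$A_theta,
       A_p = st$A_p, N = st$N)
}
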