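#' Physical constants
#'
#' CODATA values of the constants used throughout the model, plus the ATP
#' hydrolysis energy per molecule, which by convention here is `10 * k_B * T`
#' and is therefore recomputed whenever the temperature changes (unless
#' overridden explicitly in a configuration file).
#'
#' @param T absolute temperature in kelvin used to derive `Q_ATP`.
#' @param Q_ATP optional explicit override of the per-molecule ATP
#'   hydrolysis energy in joules; by default `10 * k_B * T`.
#'
#' @return A list with elements `F` (Faraday constant, C/mol), `R_u` (gas
#'   constant, J/(mol K)), `k_B` (Boltzmann constant, J/K), `N_A`
#'   (Avogadro constant, 1/mol), `q_ele` (elementary charge, C) and
#'   `Q_ATP` (J per ATP molecule).
#' @examples
#' physical_constants()$Q_ATP   # 10 kT at 310 K
#' @export
physical_constants <- function(T = 310, Q_ATP = NULL) {
  k_B <- 1.380649e-23
  list(
    F     = 96485.33212,
    R_u   = 8.31446262,
    k_B   = k_B,
    N_A   = 6.02214076e23,
    q_ele = 1.602176634e-19,
    Q_ATP = if (is.null(Q_ATP)) 10 * k_B * T else Q_ATP
  )
}
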