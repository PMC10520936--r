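#' @importFrom stats rnorm runif setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

# -- ion species ------------------------------------------------------------

#' Construct one ion species description
#'
#' @param name species label, one of "Na", "K", "Ca", "Cl".
#' @param z valence (integer, -1, +1 or +2).
#' @param D bulk diffusion coefficient, m^2/s.
#' @param a effective (hydrated) ion radius, m; enters the steric term of
#'   the modified Nernst-Planck flux.
#' @param c_i0,c_o0 initial intracellular / extracellular concentrations,
#'   mol/m^3.
#' @return A list of class `thz_ion` with the supplied fields.
#' @export
ion_species <- function(name, z, D, a, c_i0, c_o0) {
  structure(list(name = name, z = z, D = D, a = a,
                 c_i0 = c_i0, c_o0 = c_o0),
            class = "thz_ion")
}

# Literature-default ion table. Na/K initial concentrations are the printed
# whole-cell initial conditions; Ca/Cl initial concentrations, diffusion
# coefficients and hydrated radii are standard literature values (the
# species-level constants are overridable from configuration files).
default_species <- function() {
  list(
    Na = ion_species("Na", +1, 1.33e-9, 3.58e-10, c_i0 = 12,    c_o0 = 145),
    K  = ion_species("K",  +1, 1.96e-9, 3.31e-10, c_i0 = 139,   c_o0 = 4),
    Ca = ion_species("Ca", +2, 0.79e-9, 4.12e-10, c_i0 = 1e-4,  c_o0 = 2),
    Cl = ion_species("Cl", -1, 2.03e-9, 3.32e-10, c_i0 = 10,    c_o0 = 140)
  )
}

# -- parameter bundle -------------------------------------------------------

#' Default full parameter bundle for a cell type
#'
#' Builds the complete, validated configuration for one of the two shipped
#' cell types. Geometry and stimulus-facing values follow the study
#' conditions (6.6 um cell in a 19.8 um spherical domain); electroporation
#' constants are the standard asymptotic-model literature set; the
#' Na+,K+-ATPase cycle constants are literature-style defaults chosen to
#' reproduce the qualitative current-voltage behaviour of each preparation
#' (see the methods vignette), and every value can be overridden from a
#' configuration file.
#'
#' @param cell_type `"rat_neostriatal"` or `"guinea_pig_ventricular"`.
#' @return A named list of class `thz_config` with components `cell_type`,
#'   `species`, `geometry`, `electrical`, `pore`, `atpase`, `options` and
#'   `constants`.
#' @examples
#' cfg <- default_config("rat_neostriatal")
#' cfg$geometry$R_cell
#' @export
default_config <- function(cell_type = c("rat_neostriatal",
                                         "guinea_pig_ventricular")) {
  cell_type <- match.arg(cell_type)

  atpase <- if (cell_type == "rat_neostriatal") {
    list(
      k1p = 1050, k2p = 481, k3p = 2000, k4p = 320,
      k1m = 172.1, k2m = 40, k3m = 172, k4m = 40,
      kd_Nai0 = 5.0, kd_Nao0 = 70, kd_Ki0 = 16, kd_Ko0 = 1.2,
      kd_MgATP = 0.14,
      d_Nai = -0.14, d_Nao = 0.44, d_Ki = -0.14, d_Ko = 0.23,
      c_MgATP = 6.8, c_MgADP = 0.04, c_P = 1.0, pH = 7.2,
      F_c = 1.0e-12
    )
  } else {
    list(
      k1p = 1050, k2p = 481, k3p = 2000, k4p = 320,
      k1m = 172.1, k2m = 40, k3m = 172, k4m = 40,
      kd_Nai0 = 5.0, kd_Nao0 = 110, kd_Ki0 = 16, kd_Ko0 = 2.6,
      kd_MgATP = 0.14,
      d_Nai = -0.14, d_Nao = 0.70, d_Ki = -0.14, d_Ko = 0.38,
      c_MgATP = 6.8, c_MgADP = 0.04, c_P = 1.0, pH = 7.2,
      # ventricular myocytes carry ~1 pA/pF of pump current on ~150 pF of
      # membrane, i.e. a saturating whole-cell current of ~150 pA
      F_c = 2.5e-12
    )
  }

  T <- 310
  cfg <- list(
    cell_type  = cell_type,
    species    = default_species(),
    geometry   = list(R_cell = 3.3e-6, R_domain = 9.9e-6, d_mem = 5e-9,
                      N_theta = 13, N_r_in = 15, N_r_out = 15),
    electrical = list(C_m = 1e-2, g1 = 2, V_rest = -0.07,
                      sigma_i = 0.455, sigma_o = 1.2, T = T),
    pore       = list(alpha = 1e9, V_ep = 0.258, N0 = 1.5e9,
                      r_star = 0.51e-9, r_m = 0.8e-9, q_exp = 2,
                      D_p = 5e-14, F_max = 0.70e-9, r_h = 0.97e-9,
                      r_t = 0.31e-9, beta = 1.4e-19, gamma = 1.8e-11,
                      sigma_prime = 2e-2, sigma_0 = 1e-6),
    atpase     = atpase,
    options    = list(include_pump_current_in_vm = FALSE,
                      extracellular_bath = "finite",
                      negative_conc = "substep",
                      cohort_cap = 64, spawn_min = 1e-3,
                      merge_tol = 1e-3, exp_clamp = 50,
                      vep_ratio_cap = 250),
    constants  = physical_constants(T)
  )
  class(cfg) <- "thz_config"
  cfg
}

#' @export
print.thz_config <- function(x, ...) {
  cat("<thz_config>", x$cell_type, "\n")
  cat("  cell radius:", format(x$geometry$R_cell), "m in domain",
      format(x$geometry$R_domain), "m;", x$geometry$N_theta, "theta nodes\n")
  cat("  species:", paste(names(x$species), collapse = ", "), "\n")
  cat("  T =", x$electrical$T, "K; V_rest =", x$electrical$V_rest, "V\n")
  invisible(x)
}

# recursively merge user values over defaults, warning on unknown keys
merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base)) {
      warning("unknown configuration key: ", here, call. = FALSE)
      base[[k]] <- user[[k]]
    } else if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], here)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a parameter bundle from a configuration file
#'
#' Reads a JSON (canonical) or YAML (convenience) configuration file, fills
#' every unspecified key with the documented default for the requested cell
#' type, revalidates, and returns the full bundle. A minimal file may
#' contain nothing but `{"cell_type": "rat_neostriatal"}`.
#'
#' Unknown keys produce a warning (not an error); invalid values (negative
#' diffusivities and the like) raise a validation error naming the key.
#' `Q_ATP` is recomputed as `10 k_B T` from the (possibly overridden)
#' temperature unless the file sets `constants$Q_ATP` itself.
#'
#' @param path path to a `.json`, `.yaml`/`.yml` file.
#' @return A validated `thz_config` bundle.
#' @seealso [save_config()], [validate_bundle()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported configuration format: .", ext, " (use JSON or YAML)")
  )
  if (!is.list(user)) stop("configuration file must parse to a mapping")
  ct <- if (!is.null(user$cell_type)) user$cell_type else "rat_neostriatal"
  base <- default_config(ct)
  user$cell_type <- NULL
  q_atp_given <- !is.null(user$constants$Q_ATP)
  cfg <- merge_config(unclass(base), user)
  class(cfg) <- "thz_config"
  # restore ion classes lost through JSON round trips
  cfg$species <- lapply(cfg$species, function(s) {
    class(s) <- "thz_ion"; s
  })
  if (!q_atp_given) {
    cfg$constants <- physical_constants(cfg$electrical$T)
  }
  bad <- validate_bundle(cfg)
  if (length(bad)) {
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  }
  cfg
}

#' Save a parameter bundle to a configuration file
#'
#' Writes the bundle as JSON or YAML depending on the file extension. A
#' saved-then-loaded bundle is identical to the loaded original
#' (round-trip idempotence).
#'
#' @param cfg a `thz_config` bundle.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$species <- lapply(x$species, unclass)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml  = yaml::write_yaml(x, path, precision = 15),
    stop("unsupported configuration format: .", ext)
  )
  invisible(path)
}

#' Validate a parameter bundle
#'
#' Checks every type invariant of the configuration and reports violations
#' as a character vector; an empty vector means the bundle is valid. This
#' function reports rather than raises.
#'
#' @param cfg a `thz_config` bundle (or plain list with the same shape).
#' @return Character vector of human-readable violations (possibly empty).
#' @examples
#' validate_bundle(default_config())        # character(0)
#' @export
validate_bundle <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  num_pos <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      add(paste0(key, " must be a positive number"))
  }

  sp <- cfg$species
  if (length(sp) != 4 || !setequal(names(sp), c("Na", "K", "Ca", "Cl")))
    add("species: exactly the four species Na, K, Ca, Cl must be present")
  for (nm in names(sp)) {
    s <- sp[[nm]]
    if (!s$z %in% c(-1L, 1L, 2L, -1, 1, 2))
      add(paste0("species ", nm, ": valence z must be -1, +1 or +2"))
    if (!is.numeric(s$D) || s$D <= 0)
      add(paste0("species ", nm, ": diffusion coefficient D must be > 0"))
    if (!is.numeric(s$a) || s$a <= 0)
      add(paste0("species ", nm, ": effective ion radius a must be > 0"))
    if (s$c_i0 < 0 || s$c_o0 < 0)
      add(paste0("species ", nm, ": initial concentrations must be >= 0"))
  }

  g <- cfg$geometry
  if (!(g$R_cell > 0 && g$R_cell < g$R_domain))
    add("geometry: need 0 < R_cell < R_domain")
  if (!(g$d_mem > 0 && g$d_mem < g$R_cell / 50))
    add("geometry: membrane thickness d_mem must be small compared to R_cell")
  if (g$N_theta < 7 || (g$N_theta - 1) %% 6 != 0)
    add(paste0("geometry: N_theta must be >= 7 with N_theta - 1 divisible ",
               "by 6 so the reportable angles 0, pi/6, ..., pi are nodes"))
  num_pos(g$N_r_in, "geometry$N_r_in"); num_pos(g$N_r_out, "geometry$N_r_out")

  e <- cfg$electrical
  num_pos(e$C_m, "electrical$C_m")
  if (e$g1 < 0) add("electrical$g1 must be >= 0")
  num_pos(e$sigma_i, "electrical$sigma_i")
  num_pos(e$sigma_o, "electrical$sigma_o")
  num_pos(e$T, "electrical$T")

  p <- cfg$pore
  for (key in c("alpha", "V_ep", "N0", "r_star", "r_m", "q_exp", "D_p",
                "F_max", "r_h", "r_t", "beta", "gamma", "sigma_prime",
                "sigma_0")) {
    num_pos(p[[key]], paste0("pore$", key))
  }
  if (is.numeric(p$r_star) && is.numeric(p$r_m) && p$r_star > p$r_m)
    add("pore: r_star must not exceed r_m")
  if (is.numeric(p$r_star) && is.numeric(p$r_m) && is.numeric(p$q_exp) &&
      p$r_m > p$r_star && (p$r_m / p$r_star)^p$q_exp <= 1)
    add("pore: q_p = (r_m/r_star)^q_exp must exceed 1")

  a <- cfg$atpase
  for (key in c("k1p", "k2p", "k3p", "k4p", "k1m", "k2m", "k3m", "k4m",
                "kd_Nai0", "kd_Nao0", "kd_Ki0", "kd_Ko0", "kd_MgATP",
                "F_c")) {
    num_pos(a[[key]], paste0("atpase$", key))
  }
  for (key in c("c_MgATP", "c_MgADP", "c_P")) {
    if (a[[key]] < 0) add(paste0("atpase$", key, " must be >= 0"))
  }
  v
}

#' Path of a shipped default configuration file
#'
#' @param cell_type one of the shipped cell types.
#' @return Path to the installed JSON default file.
#' @export
default_config_path <- function(cell_type = c("rat_neostriatal",
                                              "guinea_pig_ventricular")) {
  cell_type <- match.arg(cell_type)
  system.file("extdata", "defaults", paste0(cell_type, ".json"),
              package = "thzpore", mustWork = TRUE)
}
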