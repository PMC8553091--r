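#' Per-bead drag coefficient of a cylindrical actin segment
#'
#' Orientation-averaged Stokes drag of a cylinder of length `l0` and diameter
#' `d` in a fluid of viscosity `eta_fluid`,
#' \deqn{\zeta_b = 4\pi\eta l_0 / [\ln(l_0/d) + 0.84].}
#' Viscosity is accepted in Pa s and converted internally
#' (1 Pa s = 1 pN s/um^2), so the result is in pN s/um.
#'
#' @param eta_fluid fluid viscosity (Pa s)
#' @param l0 segment length (um)
#' @param d segment diameter (um); must be smaller than `l0`
#' @return drag coefficient (pN s/um)
#' @examples
#' bead_drag_coefficient(0.3, 0.1, 0.007) # ~0.108
#' @export
bead_drag_coefficient <- function(eta_fluid, l0, d) {
  if (any(eta_fluid <= 0) || any(l0 <= 0) || any(d <= 0))
    stop("eta_fluid, l0 and d must all be positive")
  if (any(l0 <= d)) stop("l0 must exceed the segment diameter d")
  4 * pi * eta_fluid * l0 / (log(l0 / d) + 0.84)
}

# 1 uM corresponds to 602.214 molecules per um^3
AVOGADRO_PER_UM3_UM <- 602.214

#' Convert a molecule count in a volume to micromolar
#'
#' @param n_monomers number of molecules
#' @param volume volume (um^3)
#' @return concentration (uM); 1 uM = 602.214 molecules/um^3
#' @export
monomer_count_to_micromolar <- function(n_monomers, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  n_monomers / (AVOGADRO_PER_UM3_UM * volume)
}

#' @rdname monomer_count_to_micromolar
#' @param conc concentration (uM)
#' @export
micromolar_to_monomer_count <- function(conc, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  conc * AVOGADRO_PER_UM3_UM * volume
}

#' Maximum number of dynamic crosslinks for a given concentration
#'
#' The dynamic-crosslinker pool is expressed as an equivalent concentration
#' `C_dynamic` over the volume of the simulation box extending 9.5 um from the
#' leading edge; the cap is that concentration converted to a molecule count
#' and rounded to the nearest integer.
#'
#' @param C_dynamic dynamic crosslinker concentration (uM)
#' @param params parameter list (uses `box_width`, `box_height`)
#' @return integer cap on simultaneous dynamic crosslinks
#' @export
dynamic_crosslink_cap <- function(C_dynamic, params) {
  if (C_dynamic < 0) stop("C_dynamic must be nonnegative")
  round(C_dynamic * AVOGADRO_PER_UM3_UM * params$box_width * 9.5 *
          params$box_height)
}

#' Reference model parameters
#'
#' Returns the full parameter set of the lamellipodium model in (pN, um, s)
#' units: bead-spring actin filaments (segment rest length `l0` = 0.1 um,
#' 37 monomers per segment, persistence length 17 um), crosslinker and
#' excluded-volume springs, leading-edge pushing and motor pulling forces,
#' focal-adhesion capsule geometry and binding kinetics, and turnover
#' parameters. `kBT` defaults to 4.11e-3 pN um (room temperature). `zeta_b`
#' is always derived from `eta_fluid`, `l0` and `d_excluded` via
#' [bead_drag_coefficient()].
#'
#' @param ... named overrides of any default
#' @return a named list of class `actoflow_params`
#' @examples
#' p <- default_parameters(kappa_FA = 100)
#' p$zeta_b
#' @export
default_parameters <- function(...) {
  p <- list(
    dt = 1e-5,                 # time step (s)
    k_actin = 1000,            # actin bond spring constant (pN/um)
    l0 = 0.1,                  # actin segment rest length (um)
    l_p = 17,                  # persistence length (um)
    kBT = 4.11e-3,             # thermal energy (pN um)
    k_crosslink = 100,         # crosslinker spring constant (pN/um)
    l0_crosslink = 0.035,      # crosslinker rest length (um)
    k_excluded = 1690,         # excluded-volume constant (pN/um)
    d_excluded = 0.007,        # filament diameter / cutoff (um)
    eta_fluid = 0.3,           # cytoplasm viscosity (Pa s)
    kappa_FA = 1,              # adhesion/fluid viscosity ratio
    k_FA_bind = 10,            # adhesion binding rate (1/s)
    k_FA_unbind = 1,           # adhesion unbinding rate (1/s)
    C_dynamic = 1,             # dynamic crosslinker concentration (uM)
    k_dynamic_off = 1,         # dynamic crosslink decay rate (1/s)
    tau_age = 125,             # minimum segment lifetime (s)
    r_age = 0.2,               # post-minimum decay rate (1/s)
    filament_add_rate = 23.4,  # filaments/s
    filament_length = 1.0,     # um
    beads_per_filament = 11L,
    F_push_total = 1.5,        # pushing force per filament (pN)
    F_pull_uniform = 0.002,    # uniform per-bead pull (pN)
    F_pull_back = 0.004,       # back-mode per-bead pull (pN)
    F_pull_membrane = 0.02,    # membrane-mode per-bead pull (pN)
    pull_mode = "uniform",
    y_back_threshold = 3.25,   # back-pull onset (um)
    eps_angle = 1,             # branch angular stiffness (pN um)
    theta_0 = 70,              # branch angle (degrees)
    box_width = 2,             # um (periodic x)
    box_height = 0.2,          # um (z walls)
    confine_force = 1,         # pN
    monomers_per_segment = 37L,
    longlived_lifetime = NA_real_, # mean lifetime of "permanent" links (s)
    push_frac = 1.0,           # pushing-force scaling (0.3 in branch runs)
    fa_on = TRUE,
    fa_width = 0.25,           # capsule width (um) -> radius 0.125
    fa_length = 1.25,          # overall capsule length incl. caps (um)
    fa_height = 0.1,           # capsule height above z = 0 (um)
    fa_y_start = 1.0,          # front (leading-edge side) edge of capsule (um)
    periodic = TRUE,
    top_wall = TRUE,
    thermal_fa_drag = TRUE,    # fluctuation-dissipation with bound drag
    skin = 0.02,               # neighbor-list skin (um)
    refresh_interval = 0.025,  # dynamic-crosslink cadence (s)
    membrane_z = 0.02          # membrane-pull z band (um)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), c(names(p), "zeta_b"))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$zeta_b <- bead_drag_coefficient(p$eta_fluid, p$l0, p$d_excluded)
  if (!is.null(dots$zeta_b)) p$zeta_b <- dots$zeta_b
  p <- resolve_fa_geometry(p)
  class(p) <- "actoflow_params"
  validate_parameters(p)
  p
}

# capsule centre-line from width/length/placement: long axis along x
# (parallel to the leading edge), centred in the box, front edge at fa_y_start
resolve_fa_geometry <- function(p) {
  r <- p$fa_width / 2
  seg_len <- max(p$fa_length - p$fa_width, 0)
  cx <- p$box_width / 2
  cy <- p$fa_y_start + r
  p$fa_radius <- r
  p$fa_x0 <- cx - seg_len / 2
  p$fa_x1 <- cx + seg_len / 2
  p$fa_y0 <- cy
  p$fa_y1 <- cy
  p
}

#' Validate a parameter list
#'
#' Checks positivity/range constraints and the drag-coefficient identity.
#' @param p parameter list
#' @return `p` invisibly; stops with an informative message on violation
#' @export
validate_parameters <- function(p) {
  pos <- c("dt", "k_actin", "l0", "l_p", "kBT", "k_crosslink", "l0_crosslink",
           "k_excluded", "d_excluded", "eta_fluid", "zeta_b", "box_width",
           "box_height", "filament_length")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar")
  nonneg <- c("kappa_FA", "k_FA_bind", "k_FA_unbind", "C_dynamic",
              "k_dynamic_off", "tau_age", "r_age", "filament_add_rate",
              "F_push_total", "F_pull_uniform", "F_pull_back",
              "F_pull_membrane", "eps_angle", "confine_force", "push_frac")
  for (nm in nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("parameter '", nm, "' must be a nonnegative scalar")
  if (p$kappa_FA < 1) stop("kappa_FA must be >= 1 (1 means no adhesion)")
  if (p$theta_0 <= 0 || p$theta_0 >= 180)
    stop("theta_0 must lie strictly between 0 and 180 degrees")
  if (!p$pull_mode %in% c("uniform", "back", "membrane"))
    stop("pull_mode must be one of 'uniform', 'back', 'membrane'")
  if (p$beads_per_filament < 2)
    stop("beads_per_filament must be at least 2")
  if (p$fa_height > p$box_height)
    stop("fa_height must not exceed box_height")
  zb <- bead_drag_coefficient(p$eta_fluid, p$l0, p$d_excluded)
  if (abs(p$zeta_b - zb) > 1e-9 * zb)
    stop("zeta_b is inconsistent with eta_fluid, l0 and d_excluded")
  invisible(p)
}

#' @export
print.actoflow_params <- function(x, ...) {
  cat("actoflow model parameters (pN, um, s):\n")
  nm <- names(x)
  for (k in nm)
    cat(sprintf("  %-20s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}
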