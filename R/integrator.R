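#' Effective drag coefficient of a bead
#'
#' @param bound logical (vector): bead bound to the focal adhesion?
#' @param params parameter list
#' @return drag (pN s/um): `zeta_b`, or `kappa_FA * zeta_b` when bound
#' @export
effective_drag <- function(bound, params) {
  ifelse(bound, params$kappa_FA * params$zeta_b, params$zeta_b)
}

#' Control settings for a Brownian dynamics run
#'
#' Enables or disables force channels and stochastic remodeling events, and
#' selects the filament-insertion mode. Disabling events gives a pure
#' mechanics run (used by the mechanical-characterization rig and by
#' fixtures); `thermal = FALSE` gives zero-temperature relaxation.
#'
#' @param thermal thermal forces on
#' @param internal bonded/bending/crosslink/excluded/branch forces on
#' @param push leading-edge pushing on
#' @param motor motor pulling on
#' @param confine z-confinement on
#' @param spawn filament insertion on
#' @param expiry age-based severing and crosslink expiry on
#' @param dynamic dynamic-crosslink replenishment on
#' @param fa_kinetics adhesion binding/unbinding on
#' @param spawn_mode insertion mode (see [spawn_filaments()])
#' @return a list of flags
#' @export
run_control <- function(thermal = TRUE, internal = TRUE, push = TRUE,
                        motor = TRUE, confine = TRUE, spawn = TRUE,
                        expiry = TRUE, dynamic = TRUE, fa_kinetics = TRUE,
                        spawn_mode = "fan") {
  list(thermal = thermal, internal = internal, push = push, motor = motor,
       confine = confine, spawn = spawn, expiry = expiry, dynamic = dynamic,
       fa_kinetics = fa_kinetics, spawn_mode = spawn_mode_code(spawn_mode))
}

#' Advance a network by Brownian dynamics
#'
#' Explicit Euler-Maruyama stepping of the overdamped equation of motion
#' \eqn{\zeta_i \dot r_i = \sum F_i} at time step `params$dt`. Each step
#' applies, in fixed order: force evaluation, displacement (clamped beads
#' move at their prescribed y velocity instead), periodic wrapping, adhesion
#' binding kinetics, bond/crosslink expiry with pruning, dynamic-crosslink
#' replenishment on its 0.025 s cadence, and filament insertion. A step that
#' moves any bead farther than `l0/2` raises an instability error.
#'
#' @param state a `network_state`
#' @param duration simulated time (s); rounded down to whole steps
#' @param record_every frame-recording interval (s); 0 records only at the end
#' @param control a [run_control()] list
#' @param clamp optional list with `idx` (bead indices) and `vy`
#'   (per-clamped-bead y velocity, um/s)
#' @return list of class `bd_run`: final `state`, `frames` (each with time
#'   and a uid/x/y/z matrix of unwrapped coordinates), and `channel_sums`
#'   (per-frame totals of external force channels and the fluid/adhesion
#'   drag decomposition)
#' @export
bd_run <- function(state, duration, record_every = 0, control = run_control(),
                   clamp = NULL) {
  p <- state$params
  n_steps <- max(1L, as.integer(round(duration / p$dt)))
  rec <- if (record_every > 0) max(1L, as.integer(round(record_every / p$dt)))
         else 0L
  if (is.null(clamp)) clamp <- list(idx = integer(0), vy = numeric(0))
  out <- cpp_run(st_core(state), p, n_steps, rec, control,
                 as.integer(clamp$idx), as.numeric(clamp$vy))
  res <- list(state = st_wrap(out$state, p), frames = out$frames,
              channel_sums = out$channel_sums)
  class(res) <- "bd_run"
  res
}

#' @export
print.bd_run <- function(x, ...) {
  cat("bd_run: final t =", format(x$state$t), "s;",
      nrow(x$state$pos), "beads;", length(x$frames), "recorded frames\n")
  invisible(x)
}

#' Candidate interacting segment pairs
#'
#' Cell-list neighbor search over bond (segment) midpoints: returns every
#' pair of segments whose closest approach is below `cutoff`, excluding pairs
#' that share a bead, respecting the periodic x boundary.
#'
#' @param state a `network_state`
#' @param cutoff distance cutoff (um), default `d_excluded + skin`
#' @return integer matrix with columns i1, j1, i2, j2 (bead indices of the
#'   two segments)
#' @export
build_neighbor_pairs <- function(state,
                                 cutoff = state$params$d_excluded +
                                   state$params$skin) {
  cpp_neighbor_pairs(st_core(state), state$params, cutoff)
}

#' Count unphysical bond crossings between two frames
#'
#' Diagnostic detector for filament segments passing through each other
#' between consecutive snapshots under linearly interpolated bead motion: a
#' pair is flagged when the signed mutual-orientation determinant of the two
#' segments changes sign while the segments are close and the witness points
#' are interior. Monitoring only; no correction is applied.
#'
#' @param state_before,state_after consecutive `network_state`s over the same
#'   bead set
#' @return number of flagged pass-through events
#' @export
count_bond_crossings <- function(state_before, state_after) {
  if (nrow(state_before$pos) != nrow(state_after$pos))
    stop("frames must share the same bead set")
  segs <- do.call(rbind, lapply(state_before$fil_beads, function(b) {
    if (length(b) < 2) return(NULL)
    cbind(b[-length(b)], b[-1])
  }))
  if (is.null(segs)) return(0L)
  cpp_crossings(state_before$pos, state_after$pos, segs,
                state_before$params$box_width, state_before$params$periodic)
}
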