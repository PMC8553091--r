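#' Evaluate all force channels on a state
#'
#' Returns the per-bead force contribution of every channel entering the
#' overdamped equation of motion: bonded springs, bending, crosslink springs,
#' excluded volume between filament segments, leading-edge pushing, motor
#' pulling, z confinement, branch angular restraints, and (optionally) the
#' thermal forces for one time step. Internal channels (spring, bend,
#' crosslink, excluded, branch) each sum to zero over all beads.
#'
#' @param state a `network_state`
#' @param include_thermal draw a thermal force realization as well
#'   (consumes random numbers)
#' @return named list of n x 3 matrices (pN), one per channel
#' @export
compute_forces <- function(state, include_thermal = FALSE) {
  cpp_forces(st_core(state), state$params, include_thermal)
}

#' Potential energy by channel
#'
#' Energies (pN um) of the potential-derived channels: bond springs
#' \eqn{k/2 (d - l_0)^2}, bending \eqn{(\kappa/l_0)(1 - \cos\theta)},
#' crosslink springs, excluded-volume overlap, and branch angular restraints
#' \eqn{\epsilon (\cos\theta - \cos\theta_0)^2}. The corresponding force
#' channels are exactly minus the gradient of these terms, which the test
#' suite verifies by finite differences.
#'
#' @param state a `network_state`
#' @return named numeric vector of energies
#' @export
potential_energy <- function(state) {
  cpp_energy(st_core(state), state$params)
}

#' Closest approach between two line segments
#'
#' Minimum distance between 3D segments `a0`-`a1` and `b0`-`b1`, with the x
#' component treated under the minimum-image convention when `periodic`.
#' Ties between parallel segments resolve to the midpoint witness pair.
#'
#' @param a0,a1,b0,b1 numeric 3-vectors, segment endpoints
#' @param width periodic box width (um)
#' @param periodic apply minimum image along x
#' @return list with `distance`, the witness points `point_a`, `point_b`, and
#'   the barycentric weights `s_a`, `s_b` in `[0, 1]` measured from `a0`/`b0`
#' @export
segment_closest_approach <- function(a0, a1, b0, b1, width = Inf,
                                     periodic = FALSE) {
  cpp_seg_closest(as.numeric(a0), as.numeric(a1), as.numeric(b0),
                  as.numeric(b1), width, periodic)
}
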