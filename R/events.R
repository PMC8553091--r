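spawn_mode_code <- function(mode) {
  match(match.arg(mode, c("fan", "microspike_near", "microspike_random",
                          "branch")),
        c("fan", "microspike_near", "microspike_random", "branch")) - 1L
}

#' Insert new filaments near the leading edge
#'
#' Insertion uses a deterministic fractional accumulator at rate
#' `filament_add_rate`: the residue grows by `rate * dt` and one filament is
#' inserted for each whole unit. Fan-mode filaments are straight 11-bead,
#' 1-um chains with the pointed end at y = 0.5 um, uniform x and z, in-plane
#' angle uniform on (-70, 70) degrees about -y and out-of-plane angle uniform
#' on (-10, 10) degrees. Microspike modes alternate every other insertion
#' with an exactly vertical (axis along y) filament whose pointed-end x is
#' either 35 nm from a uniformly chosen existing bead with y < 1 um
#' (`microspike_near`) or uniform (`microspike_random`). Branch mode nucleates
#' daughters on mother beads with y in [0.20, 0.25] um at the 70-degree
#' branch angle. Fan and microspike insertions are followed by permanent
#' crosslink seeding.
#'
#' @param state a `network_state`
#' @param dt elapsed time to account for (s)
#' @param mode insertion mode
#' @return list with the updated `state` and `n_added`
#' @export
spawn_filaments <- function(state, dt, mode = "fan") {
  out <- cpp_spawn_filaments(st_core(state), state$params, dt,
                             spawn_mode_code(mode))
  list(state = st_wrap(out$state, state$params), n_added = out$n_added)
}

#' Seed permanent crosslinks onto a newly inserted filament
#'
#' Candidate pairs join a bead of filament `fil_index` to a bead of any other
#' filament at separation 0.03-0.04 um; up to five are chosen uniformly at
#' random without replacement. When `longlived_lifetime` is set the created
#' links are long-lived with exponentially distributed removal times instead
#' of permanent.
#'
#' @param state a `network_state`
#' @param fil_index filament position in the state's filament list
#' @return updated state
#' @export
seed_permanent_crosslinks <- function(state, fil_index) {
  st_wrap(cpp_seed_permanent(st_core(state), state$params, fil_index),
          state$params)
}

#' Top up dynamic crosslinks to the concentration cap
#'
#' Candidates are inter-filament bead pairs at separation 0.03-0.04 um not
#' already linked to each other; pairs are sampled uniformly without
#' replacement until the cap from [dynamic_crosslink_cap()] is reached or
#' candidates are exhausted. Each new link draws an exponential lifetime with
#' rate `k_dynamic_off`.
#'
#' @param state a `network_state`
#' @return list with the updated `state` and `n_added`
#' @export
replenish_dynamic_crosslinks <- function(state) {
  out <- cpp_replenish_dynamic(st_core(state), state$params)
  list(state = st_wrap(out$state, state$params), n_added = out$n_added)
}

#' Draw scheduled actin-bond lifetimes
#'
#' Age-dependent severing: a bond lives at least `tau_age` seconds and the
#' excess is exponential with rate `r_age`, i.e.
#' \eqn{\tau = \tau_{age} - \ln(u)/r_{age}} with u uniform on (0, 1).
#'
#' @param n number of draws
#' @param params parameter list
#' @return numeric vector of lifetimes (s)
#' @export
schedule_segment_lifetime <- function(n, params = default_parameters()) {
  params$tau_age - log(stats::runif(n)) / params$r_age
}

#' Remove expired bonds and crosslinks
#'
#' Actin bonds and crosslinks whose scheduled removal time has passed are
#' deleted; a mid-chain bond removal splits the filament (the barbed-side
#' fragment keeps the original filament id). Single-bead filaments and their
#' crosslinks are then pruned to a fixed point.
#'
#' @param state a `network_state`
#' @return updated state
#' @export
expire_bonds <- function(state) {
  st_wrap(cpp_expire(st_core(state), state$params), state$params)
}

#' Prune single-bead filaments
#' @param state a `network_state`
#' @return updated state
#' @export
prune_singletons <- function(state) {
  st_wrap(cpp_prune(st_core(state), state$params), state$params)
}

#' One step of focal-adhesion binding kinetics
#'
#' Discrete-time update: each unbound bead inside the capsule binds with
#' probability `1 - exp(-k_FA_bind dt)`, each bound bead unbinds with
#' probability `1 - exp(-k_FA_unbind dt)`, and beads outside the capsule are
#' forcibly unbound. Bound beads move (and fluctuate) with drag
#' `kappa_FA * zeta_b`.
#'
#' @param state a `network_state`
#' @param dt time step (s)
#' @return updated state
#' @export
fa_binding_update <- function(state, dt = state$params$dt) {
  st_wrap(cpp_fa_update(st_core(state), state$params, dt), state$params)
}
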