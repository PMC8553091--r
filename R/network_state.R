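#' Create an empty network state
#'
#' The state holds every bead (wrapped x, free y, confined z), the filaments
#' as ordered pointed-to-barbed bead chains with per-bond scheduled severing
#' times, all crosslinks (permanent, long-lived, dynamic, branch), branch
#' angle triplets, the simulation clock, and the event accumulators used by
#' the deterministic filament-insertion scheme.
#'
#' @param params parameter list from [default_parameters()]
#' @return a list of class `network_state`
#' @export
new_network_state <- function(params) {
  s <- list(
    pos = matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))),
    uid = numeric(0),
    birth = numeric(0),
    bound = integer(0),
    wrapn = integer(0),
    fil_beads = list(),
    fil_taus = list(),
    fil_ids = integer(0),
    xl = matrix(numeric(0), 0, 4,
                dimnames = list(NULL, c("a", "b", "type", "tau"))),
    branches = matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))),
    t = 0, resid = 0, next_refresh = params$refresh_interval,
    next_uid = 1, spawn_count = 0, next_fil_id = 1L,
    n_skipped_spawns = 0, n_overlap_kicks = 0,
    # engine RNG stream, seeded from R's RNG so set.seed() governs the run
    rngstate = cpp_rng_seed(floor(stats::runif(1) * 2^31)),
    params = params
  )
  class(s) <- "network_state"
  s
}

# strip the params element for the C++ boundary
st_core <- function(state) state[setdiff(names(state), "params")]

# reattach params and class after a C++ round trip
st_wrap <- function(core, params) {
  core$params <- params
  class(core) <- "network_state"
  core
}

#' Wrap a point into the periodic box along x
#'
#' @param point numeric 3-vector or n x 3 matrix
#' @param params parameter list (uses `box_width`, `periodic`)
#' @return same shape as `point`, with x mapped into `[0, box_width)`
#' @export
wrap_x <- function(point, params) {
  if (!isTRUE(params$periodic)) return(point)
  w <- params$box_width
  if (is.matrix(point)) {
    point[, 1] <- point[, 1] - w * floor(point[, 1] / w)
  } else {
    point[1] <- point[1] - w * floor(point[1] / w)
  }
  point
}

#' Minimum-image displacement a - b
#'
#' @param a,b numeric 3-vectors (wrapped)
#' @inheritParams wrap_x
#' @return displacement with the x component mapped into
#'   `(-box_width/2, box_width/2]`
#' @export
min_image_disp <- function(a, b, params) {
  d <- a - b
  if (isTRUE(params$periodic)) {
    w <- params$box_width
    d[1] <- d[1] - w * round(d[1] / w)
  }
  d
}

#' Test whether points lie inside the focal-adhesion capsule
#'
#' The capsule is the closed region within `fa_width/2` (in xy, minimum image
#' in x) of the centre-line segment, with z between 0 and `fa_height`.
#'
#' @param state a `network_state` (its beads are tested)
#' @return logical vector, one entry per bead
#' @export
point_in_fa <- function(state) {
  cpp_in_fa(st_core(state), state$params)
}

#' Add a straight filament to a state (fixture construction)
#'
#' Beads are placed from the pointed end at `pointed` along unit vector `dir`
#' (pointed to barbed) at spacing `l0`. Bond severing times default to
#' infinity so fixtures are inert under expiry.
#'
#' @param state a `network_state`
#' @param pointed 3-vector, pointed-end position
#' @param dir 3-vector, axis direction (normalized internally)
#' @param n_beads number of beads (>= 1; single-bead chains are allowed in
#'   fixtures, e.g. for free-diffusion checks, though the model proper prunes
#'   them)
#' @param taus optional bond severing times (length `n_beads - 1`)
#' @param spacing bead spacing, default `params$l0`
#' @return updated state
#' @export
add_filament <- function(state, pointed, dir = c(0, -1, 0),
                         n_beads = state$params$beads_per_filament,
                         taus = NULL, spacing = NULL) {
  p <- state$params
  if (is.null(spacing)) spacing <- p$l0
  dir <- dir / sqrt(sum(dir^2))
  n0 <- nrow(state$pos)
  idx <- seq_len(n_beads) + n0
  pos <- t(vapply(seq_len(n_beads) - 1,
                  function(k) pointed + k * spacing * dir, numeric(3)))
  pos <- wrap_x(pos, p)
  colnames(pos) <- c("x", "y", "z")
  state$pos <- rbind(state$pos, pos)
  state$uid <- c(state$uid, state$next_uid + seq_len(n_beads) - 1)
  state$next_uid <- state$next_uid + n_beads
  state$birth <- c(state$birth, rep(state$t, n_beads))
  state$bound <- c(state$bound, rep(0L, n_beads))
  state$wrapn <- c(state$wrapn, rep(0L, n_beads))
  if (is.null(taus)) taus <- rep(Inf, max(n_beads - 1, 0))
  state$fil_beads <- c(state$fil_beads, list(as.integer(idx)))
  state$fil_taus <- c(state$fil_taus, list(as.numeric(taus)))
  state$fil_ids <- c(state$fil_ids, state$next_fil_id)
  state$next_fil_id <- state$next_fil_id + 1L
  state
}

#' Add a crosslink between two beads
#'
#' @param state a `network_state`
#' @param a,b bead indices
#' @param type one of "permanent", "long_lived", "dynamic", "branch"
#' @param tau scheduled removal time (s), `Inf` for permanent
#' @return updated state
#' @export
add_crosslink <- function(state, a, b,
                          type = c("permanent", "long_lived", "dynamic",
                                   "branch"),
                          tau = Inf) {
  type <- match.arg(type)
  code <- match(type, c("permanent", "long_lived", "dynamic", "branch"))
  if (a == b) stop("a crosslink must join two distinct beads")
  state$xl <- rbind(state$xl, c(a, b, code, tau))
  state
}

#' Register a branch-angle triplet
#'
#' `i` and `j` are consecutive mother-filament beads (pointed side first) and
#' `k` is the daughter bead attached at `j`; the angular restraint acts on the
#' angle between (i to j) and (j to k).
#'
#' @param state a `network_state`
#' @param i,j,k bead indices
#' @return updated state
#' @export
add_branch_triplet <- function(state, i, j, k) {
  state$branches <- rbind(state$branches, c(i, j, k))
  state
}

#' Referential-integrity audit of a network state
#'
#' Verifies that every filament bead index, crosslink endpoint and branch
#' triplet references a live bead, that filaments have no repeated beads,
#' that bead-to-filament back references match, that bonded neighbor
#' distances are inside the sanity band `[0.2 l0, 5 l0]`, and that wrapped x
#' coordinates lie in `[0, box_width)`.
#'
#' @param state a `network_state`
#' @return TRUE invisibly; stops on the first violation
#' @export
audit_state <- function(state) {
  n <- nrow(state$pos)
  p <- state$params
  seen <- integer(n)
  for (f in seq_along(state$fil_beads)) {
    b <- state$fil_beads[[f]]
    if (any(b < 1 | b > n)) stop("filament ", f, " references a missing bead")
    if (anyDuplicated(b)) stop("filament ", f, " repeats a bead")
    if (length(state$fil_taus[[f]]) != length(b) - 1)
      stop("filament ", f, " has a bond/severing-time mismatch")
    seen[b] <- seen[b] + 1L
    if (length(b) >= 2) {
      d <- vapply(seq_len(length(b) - 1), function(k) {
        sqrt(sum(min_image_disp(state$pos[b[k + 1], ], state$pos[b[k], ], p)^2))
      }, numeric(1))
      if (any(d < 0.2 * p$l0 | d > 5 * p$l0))
        stop("filament ", f, " has a bond outside the sanity band")
    }
  }
  if (any(seen > 1)) stop("a bead belongs to more than one filament")
  if (nrow(state$xl)) {
    ab <- state$xl[, 1:2, drop = FALSE]
    if (any(ab < 1 | ab > n)) stop("crosslink references a missing bead")
    if (any(ab[, 1] == ab[, 2])) stop("crosslink joins a bead to itself")
  }
  if (nrow(state$branches)) {
    if (any(state$branches < 1 | state$branches > n))
      stop("branch triplet references a missing bead")
  }
  if (isTRUE(p$periodic)) {
    if (n > 0 && (any(state$pos[, 1] < 0) || any(state$pos[, 1] >= p$box_width)))
      stop("a bead x coordinate is outside [0, box_width)")
  }
  invisible(TRUE)
}

#' Bead table of a state
#' @param state a `network_state`
#' @return data.frame with one row per bead (id, filament, position,
#'   unwrapped x, bound flag, birth time)
#' @export
bead_table <- function(state) {
  n <- nrow(state$pos)
  fil <- integer(n)
  idx <- integer(n)
  for (f in seq_along(state$fil_beads)) {
    b <- state$fil_beads[[f]]
    fil[b] <- state$fil_ids[f]
    idx[b] <- seq_along(b) - 1L
  }
  data.frame(
    uid = state$uid, filament = fil, index = idx,
    x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
    x_unwrapped = state$pos[, 1] + state$wrapn * state$params$box_width,
    bound = as.logical(state$bound), birth = state$birth
  )
}

#' Total monomer count represented by a state
#'
#' Each bond (bead-spring-bead segment) represents
#' `params$monomers_per_segment` monomers.
#' @param state a `network_state`
#' @return monomer count
#' @export
monomer_count <- function(state) {
  nb <- sum(vapply(state$fil_beads, function(b) max(length(b) - 1L, 0L),
                   integer(1)))
  nb * state$params$monomers_per_segment
}

#' @export
print.network_state <- function(x, ...) {
  cat("network_state: t =", format(x$t), "s;",
      nrow(x$pos), "beads in", length(x$fil_beads), "filaments;",
      nrow(x$xl), "crosslinks;", nrow(x$branches), "branch triplets\n")
  invisible(x)
}
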