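# fixtures are generated in code; no stored data

quiet_params <- function(...) {
  default_parameters(fa_on = FALSE, ...)
}

# control with every stochastic event and external force off
mechanics_only <- function(...) {
  run_control(push = FALSE, motor = FALSE, confine = FALSE, spawn = FALSE,
              expiry = FALSE, dynamic = FALSE, fa_kinetics = FALSE, ...)
}

# n free beads (single-bead chains) scattered in a tall slab; built in bulk
free_bead_state <- function(n, params = quiet_params()) {
  s <- new_network_state(params)
  pos <- cbind(stats::runif(n, 0, params$box_width),
               stats::runif(n, 0, 10 * n * params$l0),
               params$box_height / 2)
  colnames(pos) <- c("x", "y", "z")
  s$pos <- pos
  s$uid <- seq_len(n)
  s$next_uid <- n + 1
  s$birth <- rep(0, n)
  s$bound <- rep(0L, n)
  s$wrapn <- rep(0L, n)
  s$fil_beads <- as.list(seq_len(n))
  s$fil_taus <- rep(list(numeric(0)), n)
  s$fil_ids <- seq_len(n)
  s$next_fil_id <- n + 1L
  s
}

# a filament plus a crossing filament, crosslinked and branch-restrained,
# with jittered positions: exercises every potential-derived channel
random_interacting_state <- function(jitter = 0.004) {
  s <- new_network_state(quiet_params())
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0.3, -1, 0.05), n_beads = 5)
  s <- add_filament(s, c(1.02, 1.01, 0.105), dir = c(-0.25, -1, 0), n_beads = 5)
  s$pos <- s$pos + matrix(stats::rnorm(nrow(s$pos) * 3, 0, jitter),
                          nrow(s$pos), 3)
  s$pos <- wrap_x(s$pos, s$params)
  s <- add_crosslink(s, 2, 7, "permanent")
  s <- add_branch_triplet(s, 1, 2, 8)
  s <- add_crosslink(s, 2, 8, "branch")
  s
}

total_internal_force <- function(s) {
  f <- compute_forces(s)
  f$spring + f$bend + f$crosslink + f$excluded + f$branch_angle
}

# central finite-difference gradient of the total potential energy
numeric_force <- function(s, h = 1e-7) {
  n <- nrow(s$pos)
  num <- matrix(0, n, 3)
  for (i in seq_len(n)) for (cc in 1:3) {
    sp <- s; sp$pos[i, cc] <- sp$pos[i, cc] + h
    sm <- s; sm$pos[i, cc] <- sm$pos[i, cc] - h
    num[i, cc] <- -(sum(potential_energy(sp)) - sum(potential_energy(sm))) /
      (2 * h)
  }
  num
}

# brute-force closest approach between two segments by dense sampling
brute_seg_distance <- function(a0, a1, b0, b1, n = 400) {
  ta <- seq(0, 1, length.out = n)
  pa <- outer(ta, a1 - a0) + matrix(a0, n, 3, byrow = TRUE)
  best <- Inf
  for (tb in seq(0, 1, length.out = n)) {
    pb <- b0 + tb * (b1 - b0)
    d2 <- rowSums((pa - matrix(pb, n, 3, byrow = TRUE))^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

unwrapped_pos <- function(state) {
  out <- state$pos
  out[, 1] <- out[, 1] + state$wrapn * state$params$box_width
  out
}
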