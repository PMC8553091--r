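make_frames <- function(positions_list, times, uids = NULL) {
  lapply(seq_along(positions_list), function(q) {
    pos <- positions_list[[q]]
    n <- nrow(pos)
    if (is.null(uids)) uids <- seq_len(n)
    list(t = times[q], pos = cbind(uid = uids, pos), n_beads = n)
  })
}

test_that("flow profile recovers constructed velocity fields bin-exactly", {
  # rigid translation at +0.03 um/s
  set.seed(41)
  n <- 60
  p0 <- cbind(stats::runif(n, 0, 2), stats::runif(n, 0, 4), 0.1)
  shift <- function(m, dy) sweep(m, 2, c(0, dy, 0), "+")
  fr <- make_frames(list(p0, shift(p0, 0.03), shift(p0, 0.06)), c(0, 1, 2))
  prof <- retrograde_flow_profile(fr, seq(0, 4, by = 1))
  expect_true(all(abs(prof$speed - 0.03) < 1e-12))
  # two-zone field: 0.01 um/s below y = 2, 0.05 above
  v <- ifelse(p0[, 2] < 2, 0.01, 0.05)
  p1 <- p0; p1[, 2] <- p1[, 2] + v
  fr2 <- make_frames(list(p0, p1), c(0, 1))
  prof2 <- retrograde_flow_profile(fr2, c(0, 2, 4))
  expect_equal(prof2$speed, c(0.01, 0.05))
  expect_equal(mean_retrograde_speed(fr2), mean(v))
  # static: zero
  fr3 <- make_frames(list(p0, p0), c(0, 1))
  expect_true(all(abs(retrograde_flow_profile(fr3, c(0, 4))$speed) < 1e-15))
})

test_that("density profile converts monomer counts to micromolar", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 1.01, 0.1), dir = c(1, 0, 0))  # one bin
  prof <- density_profile(s, c(0, 1, 1.5, 2))
  vol <- p$box_width * 0.5 * p$box_height
  expect_equal(prof$density[2], 370 / (602.214 * vol))
  expect_equal(prof$density[c(1, 3)], c(0, 0))
  # integral over bins recovers the monomer total
  vols <- p$box_width * diff(c(0, 1, 1.5, 2)) * p$box_height
  expect_equal(sum(prof$density * 602.214 * vols), monomer_count(s))
})

test_that("bond tension map signs distinguish compression from extension", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(0.2, 1, 0.1), dir = c(1, 0, 0), n_beads = 4)
  # at rest length: zero everywhere
  m <- bond_tension_map(s, seq(0, 2, 0.5), c(0.5, 1.5))
  expect_true(all(abs(m$tension[m$count > 0]) < 1e-12))
  # uniformly stretched: negative (extension)
  s2 <- s
  s2$pos[, 1] <- (s2$pos[, 1] - 0.2) * 1.2 + 0.2
  m2 <- bond_tension_map(s2, seq(0, 2, 0.5), c(0.5, 1.5))
  expect_true(all(m2$tension[m2$count > 0] < 0))
  # hand-built 3-bond chain matches the closed form per bond
  s3 <- new_network_state(p)
  s3 <- add_filament(s3, c(0.5, 1, 0.1), dir = c(1, 0, 0), n_beads = 4)
  s3$pos[2, 1] <- s3$pos[1, 1] + 0.09   # compressed bond
  td <- actoflow:::bond_tensions(s3)
  expect_equal(td$tension[1], 1000 * (0.1 - 0.09))
})

test_that("bending angle observable measures half-chord angles", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0, 1, 0))  # straight
  prof <- bending_angle_profile(s, c(0, 4))
  expect_equal(prof$mean_angle[1], 0, tolerance = 1e-9)
  # right angle built from two 5-bond chords
  s2 <- new_network_state(p)
  s2 <- add_filament(s2, c(0.2, 1, 0.1), dir = c(1, 0, 0))
  b <- s2$fil_beads[[1]]
  for (k in 7:11)
    s2$pos[b[k], ] <- s2$pos[b[6], ] + c(0, (k - 6) * 0.1, 0)
  prof2 <- bending_angle_profile(s2, c(0, 4))
  expect_equal(prof2$mean_angle[1], 90)
  # severed fragments are skipped
  s3 <- new_network_state(p)
  s3 <- add_filament(s3, c(1, 1, 0.1), n_beads = 5)
  prof3 <- bending_angle_profile(s3, c(0, 4))
  expect_equal(prof3$n[1], 0)
})

test_that("force balance reports exact per-bead pulls and closes", {
  set.seed(42)
  p <- default_parameters(box_width = 1, filament_add_rate = 6, tau_age = 4)
  s <- new_network_state(p)
  s <- bd_run(s, 3, record_every = 0)$state
  r <- bd_run(s, 1, record_every = 0.1)
  fb <- force_balance_summary(r)
  # uniform pull per bead is the configured magnitude, by definition
  expect_equal(fb$per_bead[fb$channel == "motor"], 0.002, tolerance = 1e-6)
  # closure: external channels balance total drag exactly (overdamped identity)
  expect_lt(abs(fb$force_y[fb$channel == "residual"]),
            1e-6 * max(abs(fb$force_y)))
  # steady-ish state: push + pull balance drag within noise once the thermal
  # channel is excluded from the external side
  ext <- sum(fb$force_y[fb$channel %in% c("leading", "motor", "confine")])
  drag <- sum(fb$force_y[fb$channel %in% c("fluid_drag", "fa_drag")])
  expect_equal(ext, drag, tolerance = 0.35 * abs(ext))
})

test_that("virial stress matches the one-bond closed form and symmetry", {
  p <- quiet_params()
  s <- new_network_state(p)
  delta <- 0.02
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0, 1, 0), n_beads = 2,
                    spacing = p$l0 + delta)
  V <- 0.5
  vir <- virial_stress(s, V)
  expect_equal(vir$sigma[2, 2], p$k_actin * delta * (p$l0 + delta) / V)
  expect_equal(vir$sigma[1, 1], 0)
  expect_equal(vir$sigma[3, 3], 0)
  expect_equal(vir$sigma, t(vir$sigma))
  expect_equal(vir$sigma_T, vir$sigma[2, 2])
  # excluding a clamped bead removes the pair
  vir2 <- virial_stress(s, V, exclude = 1)
  expect_equal(vir2$sigma_T, 0)
  # isotropic ensemble of stretched bonds: sigma_T ~ 0 by symmetry
  set.seed(43)
  s3 <- new_network_state(quiet_params(periodic = FALSE))
  for (q in 1:400) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    s3 <- add_filament(s3, c(5, 5, 5) + stats::rnorm(3), dir = dir,
                       n_beads = 2, spacing = 0.12)
  }
  vir3 <- virial_stress(s3, 1000)
  expect_lt(abs(vir3$sigma_T), 0.1 * vir3$sigma[2, 2] + 0.05 *
              sum(diag(vir3$sigma)) / 3)
})

test_that("flow and density observables are x-translation invariant", {
  set.seed(44)
  p <- default_parameters(box_width = 1, filament_add_rate = 6, tau_age = 4)
  s <- new_network_state(p)
  s <- bd_run(s, 2, record_every = 0)$state
  d1 <- density_profile(s, seq(0, 3, 0.5))
  s2 <- s
  s2$pos <- wrap_x(sweep(s2$pos, 2, c(0.37, 0, 0), "+"), p)
  d2 <- density_profile(s2, seq(0, 3, 0.5))
  expect_equal(d1$density, d2$density)
})
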