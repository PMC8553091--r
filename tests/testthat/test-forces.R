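test_that("bond springs follow Hooke's law with Newton's third law", {
  p <- quiet_params()
  s <- new_network_state(p)
  # two beads at rest separation: zero force
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0, 1, 0), n_beads = 2)
  f <- compute_forces(s)
  expect_equal(max(abs(f$spring)), 0)
  # stretched to 0.11 um: 10 pN pulling together
  s$pos[2, 2] <- s$pos[1, 2] + 0.11
  f <- compute_forces(s)
  expect_equal(f$spring[1, 2], 10)
  expect_equal(f$spring[2, 2], -10)
  # random configurations: channel sums to zero
  set.seed(4)
  for (q in 1:5) {
    sr <- random_interacting_state()
    fr <- compute_forces(sr)
    for (ch in c("spring", "bend", "crosslink", "excluded", "branch_angle"))
      expect_lt(max(abs(colSums(fr[[ch]]))), 1e-9)
  }
})

test_that("bending is zero for straight filaments and matches its gradient", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0.2, 1, 0.05), n_beads = 3)
  f <- compute_forces(s)
  expect_lt(max(abs(f$bend)), 1e-9)
  # a bent triplet exerts zero net force and zero net torque about bead 2
  s$pos[3, ] <- s$pos[2, ] + c(0.07, 0.07, 0.01)
  f <- compute_forces(s)
  expect_lt(max(abs(colSums(f$bend))), 1e-12)
  torque <- rep(0, 3)
  for (i in 1:3) {
    r <- s$pos[i, ] - s$pos[2, ]
    fo <- f$bend[i, ]
    torque <- torque + c(r[2]*fo[3] - r[3]*fo[2],
                         r[3]*fo[1] - r[1]*fo[3],
                         r[1]*fo[2] - r[2]*fo[1])
  }
  expect_lt(max(abs(torque)), 1e-12)
})

test_that("crosslink springs use the softer constant and 35 nm rest length", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(0.5, 1, 0.10), dir = c(1, 0, 0), n_beads = 2)
  s <- add_filament(s, c(0.5, 1.035, 0.10), dir = c(1, 0, 0), n_beads = 2)
  s <- add_crosslink(s, 1, 3, "permanent")
  f <- compute_forces(s)
  expect_lt(max(abs(f$crosslink)), 1e-12)   # at rest length
  s$pos[3, 2] <- s$pos[1, 2] + 0.045
  f <- compute_forces(s)
  expect_equal(f$crosslink[1, 2], 1.0)      # 100 pN/um * 0.01 um, attractive
  expect_equal(f$crosslink[3, 2], -1.0)
})

test_that("segment closest approach matches a dense-sampling oracle", {
  # parallel tie resolves at the midpoints
  r <- segment_closest_approach(c(0, 0, 0), c(1, 0, 0),
                                c(0, 0.005, 0), c(1, 0.005, 0))
  expect_equal(r$distance, 0.005)
  expect_equal(r$s_a, 0.5)
  # crossing perpendicular segments touch
  r <- segment_closest_approach(c(-1, 0, 0), c(1, 0, 0),
                                c(0, -1, 0), c(0, 1, 0))
  expect_equal(r$distance, 0)
  set.seed(8)
  for (q in 1:200) {
    a0 <- stats::rnorm(3, 0, 0.1); a1 <- a0 + stats::rnorm(3, 0, 0.1)
    b0 <- stats::rnorm(3, 0, 0.1); b1 <- b0 + stats::rnorm(3, 0, 0.1)
    got <- segment_closest_approach(a0, a1, b0, b1)$distance
    want <- brute_seg_distance(a0, a1, b0, b1)
    expect_lt(abs(got - want), 1e-4)
  }
  expect_error(segment_closest_approach(c(0,0,0), c(0,0,0),
                                        c(1,0,0), c(1,1,0)), "zero-length")
})

test_that("excluded volume repels overlapping segments by the lever rule", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(0.5, 1, 0.1), dir = c(1, 0, 0), n_beads = 2)
  # parallel segment 5 nm above: overlap of 2 nm
  s <- add_filament(s, c(0.5, 1, 0.105), dir = c(1, 0, 0), n_beads = 2)
  f <- compute_forces(s)
  mag <- sum(f$excluded[3:4, 3])
  expect_equal(mag, 1690 * 0.002, tolerance = 1e-9)
  expect_equal(colSums(f$excluded), c(0, 0, 0))
  # separation beyond 7 nm: nothing
  s$pos[3:4, 3] <- 0.108
  expect_equal(max(abs(compute_forces(s)$excluded)), 0)
  # closest point at an endpoint: that endpoint takes the whole share
  s2 <- new_network_state(p)
  s2 <- add_filament(s2, c(0.5, 1, 0.1), dir = c(1, 0, 0), n_beads = 2)
  s2 <- add_filament(s2, c(0.5 - 0.002, 1, 0.1), dir = c(-1, 0, 0), n_beads = 2)
  f2 <- compute_forces(s2)
  expect_equal(f2$excluded[2, ], c(0, 0, 0))  # far endpoint unloaded
  expect_gt(abs(f2$excluded[1, 1]), 0)
})

test_that("leading-edge pushing acts per filament along barbed-to-pointed", {
  p <- quiet_params()
  s <- new_network_state(p)
  # filament entirely behind the push region
  s <- add_filament(s, c(1, 2, 0.1), dir = c(0, 1, 0))
  f <- compute_forces(s)
  expect_equal(max(abs(f$leading)), 0)
  # pointed end above y = 0, barbed reaching into the region: push on
  s2 <- new_network_state(p)
  s2 <- add_filament(s2, c(1, 0.5, 0.1), dir = c(0, -1, 0))
  f2 <- compute_forces(s2)
  expect_equal(f2$leading[, 2], rep(1.5 / 11, 11))  # 0.136 pN, retrograde +y
  expect_equal(sum(f2$leading[, 2]), 1.5)
  # severed fragment: total per filament fixed, share adapts to bead count
  s3 <- new_network_state(p)
  s3 <- add_filament(s3, c(1, 0.3, 0.1), dir = c(0, -1, 0), n_beads = 5)
  f3 <- compute_forces(s3)
  expect_equal(f3$leading[, 2], rep(1.5 / 5, 5))
})

test_that("motor pulling modes target the documented bead sets", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 0.5, 0.1), dir = c(0, 1, 0))  # y in [0.5, 1.5]
  f <- compute_forces(s)
  expect_equal(f$motor[, 2], rep(0.002, 11))
  expect_equal(colSums(f$motor), c(0, 0.002 * 11, 0))
  # back mode: nothing below the 3.25 um threshold
  s$params$pull_mode <- "back"
  expect_equal(max(abs(compute_forces(s)$motor)), 0)
  s2 <- s
  s2$pos[, 2] <- s2$pos[, 2] + 3.2   # beads from 3.7 up
  f2 <- compute_forces(s2)
  expect_equal(f2$motor[, 2], rep(0.004, 11))
  # membrane mode: only beads near the substrate, outside the adhesion
  p3 <- default_parameters(pull_mode = "membrane")
  s3 <- new_network_state(p3)
  s3 <- add_filament(s3, c(1, 3, 0.01), dir = c(0, 1, 0))   # low, outside FA
  s3 <- add_filament(s3, c(1, 3, 0.15), dir = c(0, 1, 0))   # too high
  fa_centre <- c((p3$fa_x0 + p3$fa_x1) / 2, p3$fa_y0, 0.01)
  s3 <- add_filament(s3, fa_centre, dir = c(0, 1, 0), n_beads = 2)  # inside FA
  f3 <- compute_forces(s3)
  expect_equal(sqrt(sum(f3$motor[1, ]^2)), 0.02)  # 0.02 pN along the axis
  expect_equal(max(abs(f3$motor[12:22, ])), 0)
  expect_equal(max(abs(f3$motor[23, ])), 0)       # inside capsule: exempt
})

test_that("confinement pushes beads back into the slab", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 1, 0.1), n_beads = 1)
  s <- add_filament(s, c(1, 1, -0.01), n_beads = 1)
  s <- add_filament(s, c(1, 1, 0.30), n_beads = 1)
  f <- compute_forces(s)
  expect_equal(f$confine[1, ], c(0, 0, 0))
  expect_equal(f$confine[2, ], c(0, 0, 1))
  expect_equal(f$confine[3, ], c(0, 0, -1))
  # buckling variant: no top wall
  s$params$top_wall <- FALSE
  f2 <- compute_forces(s)
  expect_equal(f2$confine[3, ], c(0, 0, 0))
  expect_equal(f2$confine[2, ], c(0, 0, 1))
})

test_that("branch restraint is zero at 70 degrees and gradient-consistent", {
  p <- quiet_params()
  th <- 70 * pi / 180
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 1, 0.1), dir = c(0, 1, 0), n_beads = 2)
  # daughter pointed end offset from the junction along its own axis
  s <- add_filament(s, c(1, 1 + p$l0, 0.1) +
                      p$d_excluded * c(sin(th), cos(th), 0),
                    dir = c(sin(th), cos(th), 0), n_beads = 2)
  s <- add_branch_triplet(s, 1, 2, 3)
  f <- compute_forces(s)
  expect_lt(max(abs(f$branch_angle)), 1e-12)
  # bend to 90 degrees: net force and torque vanish; FD gradient agrees
  s$pos[3, ] <- s$pos[2, ] + c(p$l0, 0, 0)
  s$pos[4, ] <- s$pos[3, ] + c(p$l0, 0, 0)
  f <- compute_forces(s)
  expect_lt(max(abs(colSums(f$branch_angle))), 1e-12)
  num <- numeric_force(s)
  expect_lt(max(abs(num - total_internal_force(s))), 1e-6 * max(abs(num)))
})

test_that("potential channels match finite-difference gradients on random fixtures", {
  set.seed(12)
  for (q in 1:25) {
    s <- random_interacting_state()
    fa <- total_internal_force(s)
    num <- numeric_force(s)
    scale <- max(abs(num), 1)
    expect_lt(max(abs(num - fa)) / scale, 1e-6)
  }
})

test_that("thermal forces satisfy the fluctuation-dissipation variance", {
  set.seed(5)
  p <- quiet_params()
  s <- free_bead_state(500, p)
  vals <- numeric(0)
  for (q in 1:6)
    vals <- c(vals, as.numeric(compute_forces(s, include_thermal = TRUE)$thermal))
  expect_equal(mean(vals), 0,
               tolerance = 5 * sqrt(var(vals) / length(vals)) / 1)
  expect_equal(var(vals), 2 * p$kBT * p$zeta_b / p$dt, tolerance = 0.03)
  # bound beads fluctuate with the elevated adhesion drag
  p2 <- default_parameters(kappa_FA = 100)
  s2 <- new_network_state(p2)
  s2 <- add_filament(s2, c((p2$fa_x0 + p2$fa_x1) / 2, p2$fa_y0, 0.05),
                     n_beads = 1)
  s2$bound[1] <- 1L
  vv <- replicate(4000, compute_forces(s2, include_thermal = TRUE)$thermal[1, 1])
  expect_equal(var(vv), 2 * p2$kBT * 100 * p2$zeta_b / p2$dt, tolerance = 0.08)
})

test_that("equilibrium bend-angle fluctuations recover l0/l_p equipartition", {
  # long BD run of one filament: <theta^2> for consecutive segments ~ 2 l0/l_p
  set.seed(21)
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 5, 0.1), dir = c(0, 1, 0), n_beads = 5)
  s <- bd_run(s, 0.5, record_every = 0, control = mechanics_only())$state
  acc <- 0; n <- 0
  for (q in 1:300) {
    s <- bd_run(s, 0.01, record_every = 0, control = mechanics_only())$state
    pos <- unwrapped_pos(s)
    tv <- diff(pos[s$fil_beads[[1]], ])
    tv <- tv / sqrt(rowSums(tv^2))
    cth <- rowSums(tv[-nrow(tv), ] * tv[-1, ])
    acc <- acc + sum(acos(pmin(1, cth))^2); n <- n + length(cth)
  }
  expect_equal(acc / n, 2 * p$l0 / p$l_p, tolerance = 0.1)
})

test_that("zero-temperature relaxation monotonically reduces energy", {
  set.seed(9)
  s <- random_interacting_state(jitter = 0.01)
  ctrl <- mechanics_only(thermal = FALSE)
  e_prev <- sum(potential_energy(s))
  for (q in 1:10) {
    s <- bd_run(s, 20 * s$params$dt, record_every = 0, control = ctrl)$state
    e <- sum(potential_energy(s))
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})
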