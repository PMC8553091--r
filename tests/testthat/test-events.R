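test_that("filament insertion uses a deterministic rate accumulator", {
  set.seed(2)
  p <- quiet_params()
  s <- new_network_state(p)
  # rate 23.4/s over 10 s inserts exactly 234 filaments
  out <- spawn_filaments(s, 10)
  expect_equal(out$n_added, 234)
  expect_equal(length(out$state$fil_beads), 234)
  # every pointed end sits exactly at y = 0.5
  pointed <- vapply(out$state$fil_beads, function(b) b[1], integer(1))
  expect_true(all(abs(out$state$pos[pointed, 2] - 0.5) < 1e-12))
  # 11 beads, 1 um long, collinear at l0 spacing
  b <- out$state$fil_beads[[1]]
  expect_equal(length(b), 11)
  d <- diff(unwrapped_pos(out$state)[b, ])
  expect_true(all(abs(sqrt(rowSums(d^2)) - p$l0) < 1e-12))
  expect_true(audit_state(out$state))
})

test_that("insertion angles are uniform in the fan and tilt windows", {
  set.seed(6)
  p <- quiet_params()
  s <- new_network_state(p)
  out <- spawn_filaments(s, 2000 / p$filament_add_rate)
  st <- out$state
  # axis construction: d = (sin phi, -cos phi cos psi, -cos phi sin psi) l0
  ang <- t(vapply(st$fil_beads, function(b) {
    d <- min_image_disp(st$pos[b[2], ], st$pos[b[1], ], p)  # pointed -> barbed
    c(asin(max(-1, min(1, d[1] / p$l0))) * 180 / pi,  # in-plane fan angle
      atan2(-d[3], -d[2]) * 180 / pi)                 # out-of-plane tilt
  }, numeric(2)))
  expect_true(all(ang[, 1] >= -70 - 1e-9 & ang[, 1] <= 70 + 1e-9))
  expect_true(all(ang[, 2] >= -10 - 1e-9 & ang[, 2] <= 10 + 1e-9))
  ks <- stats::ks.test(ang[, 1], "punif", -70, 70)
  expect_gt(ks$p.value, 1e-3)
})

test_that("permanent crosslink seeding respects the window and the cap of five", {
  p <- quiet_params()
  # an isolated first filament gets nothing
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 0.5, 0.1))
  s <- seed_permanent_crosslinks(s, 1)
  expect_equal(nrow(s$xl), 0)
  # a ladder of candidates: more than five in the 0.03-0.04 window -> exactly 5
  set.seed(13)
  s <- new_network_state(p)
  s <- add_filament(s, c(0.5, 1, 0.10), dir = c(1, 0, 0), n_beads = 11)
  s <- add_filament(s, c(0.5, 1.035, 0.10), dir = c(1, 0, 0), n_beads = 11)
  s <- seed_permanent_crosslinks(s, 2)
  expect_equal(nrow(s$xl), 5)
  expect_true(all(s$xl[, "type"] == 1))
  expect_true(all(!is.finite(s$xl[, "tau"])))
  # created links all span the selection window
  d <- vapply(seq_len(nrow(s$xl)), function(q) {
    sqrt(sum(min_image_disp(s$pos[s$xl[q, 1], ], s$pos[s$xl[q, 2], ], p)^2))
  }, numeric(1))
  expect_true(all(d >= 0.03 & d <= 0.04))
  # long-lived variant: finite exponential removal times
  p2 <- quiet_params(longlived_lifetime = 20)
  s2 <- new_network_state(p2)
  s2 <- add_filament(s2, c(0.5, 1, 0.10), dir = c(1, 0, 0), n_beads = 11)
  s2 <- add_filament(s2, c(0.5, 1.035, 0.10), dir = c(1, 0, 0), n_beads = 11)
  s2 <- seed_permanent_crosslinks(s2, 2)
  expect_true(all(s2$xl[, "type"] == 2))
  expect_true(all(is.finite(s2$xl[, "tau"])))
})

test_that("dynamic crosslinks replenish to the cap with exponential lifetimes", {
  set.seed(14)
  # tiny box so the cap is small and reachable
  p <- quiet_params(box_width = 0.5, box_height = 0.05,
                    fa_height = 0.05, C_dynamic = 0.05)
  cap <- dynamic_crosslink_cap(p$C_dynamic, p)
  expect_gt(cap, 0)
  s <- new_network_state(p)
  for (q in 1:12)
    s <- add_filament(s, c(0.25, 0.5 + 0.035 * q, 0.02), dir = c(1, 0, 0),
                      n_beads = 11)
  out <- replenish_dynamic_crosslinks(s)
  n_dyn <- sum(out$state$xl[, "type"] == 3)
  expect_lte(n_dyn, cap)
  expect_equal(out$n_added, n_dyn)
  # already at cap: no additions
  out2 <- replenish_dynamic_crosslinks(out$state)
  expect_equal(out2$n_added, 0)
  # dynamic links never join beads of the same filament
  xl <- out$state$xl
  fil_of <- integer(nrow(out$state$pos))
  for (f in seq_along(out$state$fil_beads))
    fil_of[out$state$fil_beads[[f]]] <- f
  dyn <- xl[xl[, "type"] == 3, , drop = FALSE]
  expect_true(all(fil_of[dyn[, 1]] != fil_of[dyn[, 2]]))
  # lifetimes are exponential with mean 1/k_dynamic_off
  tau <- dyn[, "tau"] - out$state$t
  expect_true(all(tau > 0))
})

test_that("segment lifetimes are shifted-exponential with the stated moments", {
  set.seed(15)
  p <- default_parameters()
  tau <- schedule_segment_lifetime(1e5, p)
  expect_true(all(tau >= 125))
  expect_equal(mean(tau), 125 + 1 / 0.2, tolerance = 0.01)
  expect_equal(min(tau), 125, tolerance = 1e-3)
})

test_that("expiry removes bonds, splits chains, and pruning cascades", {
  p <- quiet_params()
  s <- new_network_state(p)
  s <- add_filament(s, c(1, 0.5, 0.1), taus = c(0.5, rep(Inf, 9)))
  s$t <- 1
  s2 <- expire_bonds(s)
  # end-bond expiry leaves a 10-bead filament; the orphan bead is pruned
  expect_equal(vapply(s2$fil_beads, length, integer(1)), 10L)
  expect_equal(nrow(s2$pos), 10)
  # nothing expired: state unchanged
  s3 <- expire_bonds(s2)
  expect_equal(s3$pos, s2$pos)
  expect_equal(s3$fil_beads, s2$fil_beads)
  # cascade: chain of 3 beads where both bonds expire; crosslinks to a
  # surviving filament are removed with their beads
  s4 <- new_network_state(p)
  s4 <- add_filament(s4, c(1, 1, 0.1), n_beads = 3, taus = c(0.2, 0.4))
  s4 <- add_filament(s4, c(1.05, 1, 0.1), n_beads = 2)
  s4 <- add_crosslink(s4, 2, 4, "permanent")
  s4 <- add_crosslink(s4, 1, 5, "dynamic", tau = Inf)
  s4$t <- 1
  s5 <- expire_bonds(s4)
  expect_equal(length(s5$fil_beads), 1)
  expect_equal(nrow(s5$pos), 2)
  expect_equal(nrow(s5$xl), 0)
  expect_true(audit_state(s5))
})

test_that("adhesion binding kinetics reach the two-state equilibrium", {
  set.seed(16)
  p <- default_parameters(kappa_FA = 100)
  s <- new_network_state(p)
  for (q in 1:40)
    s <- add_filament(s, c(stats::runif(1, p$fa_x0, p$fa_x1),
                           p$fa_y0 + stats::runif(1, -0.05, 0.05),
                           stats::runif(1, 0.01, 0.09)), n_beads = 1)
  s <- add_filament(s, c(1, 5, 0.1), n_beads = 1)  # far outside
  # static beads, kinetics only
  acc <- 0; n <- 0
  st <- fa_binding_update(s, 2)   # long step to approach equilibrium fast
  for (q in 1:600) {
    st <- fa_binding_update(st, 0.05)
    acc <- acc + sum(st$bound[1:40]); n <- n + 40
    expect_equal(st$bound[41], 0L)   # outside the capsule: never binds
  }
  expect_equal(acc / n, 10 / 11, tolerance = 0.03)
  # effective drag honours the bound flag
  expect_equal(effective_drag(c(FALSE, TRUE), p),
               c(p$zeta_b, 100 * p$zeta_b))
})

test_that("vertical insertion modes alternate and place pointed ends correctly", {
  set.seed(17)
  p <- quiet_params()
  s <- new_network_state(p)
  out <- spawn_filaments(s, 40 / p$filament_add_rate, mode = "microspike_random")
  st <- out$state
  vertical <- vapply(st$fil_beads, function(b) {
    d <- min_image_disp(st$pos[b[2], ], st$pos[b[1], ], p)
    abs(d[1]) < 1e-12 && abs(d[3]) < 1e-12
  }, logical(1))
  # deterministic alternation: half vertical
  expect_equal(sum(vertical), length(vertical) %/% 2)
  # vertical filaments have constant x along the chain
  vb <- st$fil_beads[[which(vertical)[1]]]
  expect_equal(diff(range(st$pos[vb, 1])), 0)
  # near-existing mode: pointed x exactly 35 nm from an existing bead
  set.seed(18)
  s2 <- new_network_state(p)
  s2 <- add_filament(s2, c(1.2, 0.5, 0.1))
  out2 <- spawn_filaments(s2, 2 / p$filament_add_rate,
                          mode = "microspike_near")
  st2 <- out2$state
  newv <- setdiff(seq_along(st2$fil_beads), 1)
  vert2 <- newv[vapply(st2$fil_beads[newv], function(b) {
    d <- st2$pos[b[2], ] - st2$pos[b[1], ]
    abs(d[1]) < 1e-9 && abs(d[3]) < 1e-9
  }, logical(1))]
  expect_gte(length(vert2), 1)
  # anchor may be any pre-existing bead with y < 1 (including the fan
  # filament inserted just before)
  px <- st2$pos[st2$fil_beads[[vert2[1]]][1], 1]
  others <- setdiff(seq_len(nrow(st2$pos)), st2$fil_beads[[vert2[1]]])
  anchors <- st2$pos[others, 1][st2$pos[others, 2] < 1]
  dx <- abs(px - anchors)
  dx <- pmin(dx, p$box_width - dx)
  expect_equal(min(abs(dx - 0.035)), 0, tolerance = 1e-9)
})

test_that("branch nucleation builds 70-degree in-plane daughters", {
  set.seed(19)
  p <- quiet_params(push_frac = 0.3)
  s <- new_network_state(p)
  # mother filament crossing the nucleation window y in [0.20, 0.25]
  s <- add_filament(s, c(1, 0.62, 0.1), dir = c(0, -1, 0))
  out <- spawn_filaments(s, 3 / p$filament_add_rate, mode = "branch")
  st <- out$state
  expect_gt(out$n_added, 0)
  expect_equal(nrow(st$branches), out$n_added)
  expect_equal(sum(st$xl[, "type"] == 4), out$n_added)
  for (q in seq_len(nrow(st$branches))) {
    i <- st$branches[q, 1]; j <- st$branches[q, 2]; k <- st$branches[q, 3]
    u <- min_image_disp(st$pos[j, ], st$pos[i, ], p)
    v <- min_image_disp(st$pos[k, ], st$pos[j, ], p)
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(ang, 70, tolerance = 1e-6)
    # daughter initial axis lies in the xy plane
    daughter <- NULL
    for (f in seq_along(st$fil_beads))
      if (st$fil_beads[[f]][1] == k) daughter <- st$fil_beads[[f]]
    expect_false(is.null(daughter))
    expect_equal(diff(range(st$pos[daughter, 3])), 0, tolerance = 1e-9)
  }
  # mother bead window respected
  moms <- st$branches[, 2]
  expect_true(all(s$pos[moms, 2] >= 0.20 - 1e-9 &
                  s$pos[moms, 2] <= 0.25 + 1e-9))
  # no eligible mother: insertion skipped and logged
  s3 <- new_network_state(p)
  out3 <- spawn_filaments(s3, 1 / p$filament_add_rate, mode = "branch")
  expect_equal(out3$n_added, 0)
  expect_gt(out3$state$n_skipped_spawns, 0)
})

test_that("with insertion disabled and finite lifetimes the network empties", {
  set.seed(20)
  p <- quiet_params(tau_age = 0.2, r_age = 5)
  s <- new_network_state(p)
  out <- spawn_filaments(s, 5 / p$filament_add_rate)
  st <- out$state
  ctrl <- run_control(spawn = FALSE, fa_kinetics = FALSE, dynamic = FALSE)
  st <- bd_run(st, 1.5, record_every = 0, control = ctrl)$state
  expect_equal(nrow(st$pos), 0)
  expect_equal(length(st$fil_beads), 0)
})
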