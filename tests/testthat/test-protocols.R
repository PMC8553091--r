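test_that("modulus_at_strain interpolates the secant modulus exactly", {
  curve <- data.frame(strain = seq(0, 0.5, 0.1), stress = 700 * seq(0, 0.5, 0.1))
  expect_equal(modulus_at_strain(curve), 700)
  expect_equal(modulus_at_strain(curve, 0.35), 700)
  expect_error(modulus_at_strain(curve, 0.7), "does not cover")
})

test_that("patch extraction tiles, reconnects and cuts with full integrity", {
  set.seed(72)
  p <- default_parameters(box_width = 1, filament_add_rate = 6, tau_age = 4)
  s <- bd_run(new_network_state(p), 3, record_every = 0)$state
  n0 <- nrow(s$pos)
  nxl0 <- nrow(s$xl)
  out <- extract_mechanical_patch(s, equil_time = 0.5, y_cut = c(-0.5, 2.5))
  pp <- out$state
  # roughly twice the beads, minus cut losses
  expect_gt(nrow(pp$pos), 1.5 * n0)
  expect_lte(nrow(pp$pos), 2 * n0)
  # crosslinks roughly doubled (non-wrapping links duplicate, wrapped links
  # reconnect once, cut links vanish)
  expect_gt(nrow(pp$xl), nxl0)
  # no bond or crosslink references a removed bead; chains intact
  expect_true(audit_state(pp))
  expect_false(pp$params$periodic)
  # x now spans about twice the original box
  expect_gt(diff(range(pp$pos[, 1])), 1.4 * p$box_width)
  # disconnected fragments are detected and reported
  expect_gte(out$n_fragments, 1)
})

test_that("the synthetic lattice patch behaves as a nonlinear elastic solid", {
  set.seed(71)
  patch <- build_synthetic_patch()
  expect_true(audit_state(patch))
  ext <- uniaxial_test(patch, "extension", strain_rate = 0.4, n_samples = 6)
  # strain-zero sample carries only (small) prestress
  expect_lt(abs(ext$stress[1]), 0.1 * max(abs(ext$stress)))
  # stress-stiffening: secant modulus grows with strain
  expect_gt(modulus_at_strain(ext, 0.4), modulus_at_strain(ext, 0.1))
  # compression is much softer than extension (filament buckling)
  set.seed(71)
  comp <- uniaxial_test(patch, "compression", strain_rate = 0.4,
                        n_samples = 3, strain_max = 0.25)
  expect_gt(modulus_at_strain(ext, 0.2), modulus_at_strain(comp, 0.2))
  # stiffer actin bonds stiffen the network
  set.seed(71)
  p2 <- default_parameters(periodic = FALSE, fa_on = FALSE, box_width = 2.6,
                           k_actin = 3000)
  patch2 <- build_synthetic_patch(p2)
  ext2 <- uniaxial_test(patch2, "extension", strain_rate = 0.4,
                        n_samples = 3, strain_max = 0.25)
  expect_gt(modulus_at_strain(ext2, 0.2), modulus_at_strain(ext, 0.2))
  # without the top wall, compression shows a buckling peak
  set.seed(75)
  comp_nw <- uniaxial_test(patch, "compression", strain_rate = 0.4,
                           n_samples = 8, top_wall = FALSE)
  expect_lt(which.max(comp_nw$stress), nrow(comp_nw))
})

test_that("steady-state detection reports a plateau on a capped network", {
  set.seed(73)
  p <- default_parameters(box_width = 1, filament_add_rate = 3, tau_age = 2.5)
  out <- run_to_steady_state(new_network_state(p), max_time = 20,
                             window = 2.5, tol = 0.12)
  expect_true(out$converged)
  expect_gt(nrow(out$history), 1)
})

test_that("arc scenario distinguishes permanent from long-lived crosslinking", {
  # smoke-scale: rear adhesion, strong clutch; the long-lived variant must
  # produce finite-lifetime links, the permanent variant must not
  set.seed(74)
  params <- default_parameters(box_width = 1, filament_add_rate = 6,
                               tau_age = 3, kappa_FA = 250,
                               fa_y_start = 1.375, C_dynamic = 10)
  perm <- arc_scenario(C_dynamic_values = 10, longlived_lifetime = NA,
                       params = params, equil_time = 1.5, measure_time = 0.5)
  ll <- arc_scenario(C_dynamic_values = 10, longlived_lifetime = 20,
                     params = params, equil_time = 1.5, measure_time = 0.5)
  xp <- perm[["10"]]$state$xl
  xl <- ll[["10"]]$state$xl
  expect_true(any(xp[, "type"] == 1))
  expect_false(any(xp[, "type"] == 2))
  expect_true(any(xl[, "type"] == 2))
  expect_false(any(xl[, "type"] == 1))
  expect_true(all(is.finite(xl[xl[, "type"] == 2, "tau"])))
  # diagnostics come back well-formed
  expect_s3_class(perm[["10"]]$density, "data.frame")
  expect_true(is.finite(perm[["10"]]$peak_y))
})

test_that("microspike scenario seeds vertical bundles; fan control does not", {
  set.seed(76)
  params <- default_parameters(box_width = 1, filament_add_rate = 6,
                               tau_age = 3, kappa_FA = 250,
                               fa_y_start = 1.375, C_dynamic = 10)
  ms <- microspike_scenario("near_existing", params = params,
                            equil_time = 2, measure_time = 0.5)
  expect_true(is.finite(ms$cv))
  # half the insertions are vertical, so the near-vertical filament fraction
  # (in-plane axis within 10 degrees of the flow direction, generous to
  # thermal jitter) far exceeds the all-fan control's 14% window share
  near_vertical_fraction <- function(st) {
    n <- 0; nv <- 0
    for (b in st$fil_beads) {
      if (length(b) < 2) next
      d <- min_image_disp(st$pos[b[2], ], st$pos[b[1], ], st$params)
      phi <- atan2(abs(d[1]), abs(d[2])) * 180 / pi
      n <- n + 1
      if (phi < 20) nv <- nv + 1
    }
    nv / max(n, 1)
  }
  frac_ms <- near_vertical_fraction(ms$state)
  set.seed(76)
  ctrl_run <- bd_run(new_network_state(params), 2.5, record_every = 0)
  frac_ctrl <- near_vertical_fraction(ctrl_run$state)
  expect_gt(frac_ms, frac_ctrl)
  expect_gt(frac_ms, 0.25)  # fan-only window share of +/-20 degrees is 2/7
})
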