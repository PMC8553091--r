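#' Desk-scale study profile
#'
#' A reduced problem size for interactive use and testing: a 1-um-wide box,
#' proportionally reduced filament addition rate, a short minimum segment
#' lifetime and short equilibration/measurement windows. The physics
#' (force laws, kinetics, per-filament and per-bead force magnitudes) is
#' unchanged; only the extent of the network and the sampled durations
#' shrink, so desk runs support qualitative and ordering checks, not the
#' full-scale flow-speed magnitudes.
#'
#' @param ... overrides passed through to [default_parameters()]
#' @return list with `params` and the suggested `equil_time`,
#'   `measure_time`, `record_every` (s)
#' @export
desk_profile <- function(...) {
  params <- default_parameters(
    box_width = 1, filament_add_rate = 6, tau_age = 10, ...)
  list(params = params, equil_time = 12, measure_time = 6,
       record_every = 0.5)
}

#' Evolve a network to steady state
#'
#' Runs Brownian dynamics in windows and declares a plateau when the
#' relative change of the windowed means of bead count and network length
#' (99th percentile of y) both drop below `tol`.
#'
#' @param state a `network_state`
#' @param max_time time budget (s)
#' @param window comparison window (s)
#' @param tol relative-change threshold
#' @param control a [run_control()] list
#' @return list with `state`, `converged`, and the window history
#' @export
run_to_steady_state <- function(state, max_time, window = 5, tol = 0.02,
                                control = run_control()) {
  hist <- data.frame(t = numeric(0), beads = numeric(0), len = numeric(0))
  prev <- NULL
  elapsed <- 0
  while (elapsed < max_time) {
    run <- bd_run(state, window, record_every = window / 5, control = control)
    state <- run$state
    elapsed <- elapsed + window
    nb <- mean(vapply(run$frames, function(f) f$n_beads, numeric(1)))
    len <- mean(vapply(run$frames, function(f) {
      y <- f$pos[, 3]
      if (length(y)) stats::quantile(y, 0.99) else 0
    }, numeric(1)))
    hist <- rbind(hist, data.frame(t = state$t, beads = nb, len = len))
    if (!is.null(prev) && prev$beads > 0 && prev$len > 0) {
      if (abs(nb - prev$beads) / prev$beads < tol &&
          abs(len - prev$len) / prev$len < tol)
        return(list(state = state, converged = TRUE, history = hist))
    }
    prev <- list(beads = nb, len = len)
  }
  list(state = state, converged = FALSE, history = hist)
}

#' Focal-adhesion strength sweep
#'
#' For each adhesion-to-cytoplasm viscosity ratio `kappa_FA`, grows a network
#' from scratch to (approximate) steady state, then records frames over a
#' measurement window and reports the all-bead mean retrograde flow speed
#' together with the raw frames and force-channel records.
#'
#' @param kappas vector of `kappa_FA` values
#' @param params base parameter list
#' @param equil_time equilibration time (s)
#' @param measure_time measurement window (s)
#' @param record_every frame interval during measurement (s)
#' @param control a [run_control()] list
#' @param paired use common random numbers: restore the RNG state before
#'   each kappa so all runs see identical stochastic inputs (insertion
#'   geometry, thermal kicks) and differences reflect the adhesion strength
#'   alone. Greatly reduces the between-kappa comparison noise at reduced
#'   scale.
#' @return list with `summary` (data.frame of kappa and mean speed in um/s)
#'   and per-kappa `runs` (final state, frames, channel sums)
#' @export
run_clutch_sweep <- function(kappas, params = desk_profile()$params,
                             equil_time = 12, measure_time = 6,
                             record_every = 0.5,
                             control = run_control(), paired = FALSE) {
  runs <- list()
  speeds <- numeric(length(kappas))
  if (paired) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    rng0 <- get(".Random.seed", envir = globalenv())
  }
  for (q in seq_along(kappas)) {
    if (paired) assign(".Random.seed", rng0, envir = globalenv())
    p <- params
    p$kappa_FA <- kappas[q]
    state <- new_network_state(p)
    eq <- bd_run(state, equil_time, record_every = 0, control = control)
    me <- bd_run(eq$state, measure_time, record_every = record_every,
                 control = control)
    speeds[q] <- mean_retrograde_speed(me$frames)
    runs[[q]] <- list(kappa_FA = kappas[q], state = me$state,
                      frames = me$frames, channel_sums = me$channel_sums)
  }
  list(summary = data.frame(kappa_FA = kappas, speed = speeds), runs = runs)
}

#' Simulated cytochalasin-D treatment
#'
#' From a steady-state network, filament insertion and leading-edge pushing
#' are switched off (polymerization halt); the run continues and the
#' retrograde flow speed measured in the window `wait + c(0, measure)` after
#' the switch is compared to the pre-treatment speed. Both speeds are
#' all-bead averages.
#'
#' @param state a steady-state `network_state`
#' @param baseline_time window for the pre-treatment speed (s)
#' @param wait delay between the switch and the measurement window (s)
#' @param measure length of the measurement window (s)
#' @param record_every frame interval (s)
#' @param control a [run_control()] list for the baseline phase
#' @return list with `ratio` (= v_cytoD / v), both speeds, and the final state
#' @export
cytochalasin_protocol <- function(state, baseline_time = 5, wait = 30,
                                  measure = 5, record_every = 0.5,
                                  control = run_control()) {
  base <- bd_run(state, baseline_time, record_every = record_every,
                 control = control)
  v0 <- mean_retrograde_speed(base$frames)
  ctrl_cyto <- control
  ctrl_cyto$spawn <- FALSE
  ctrl_cyto$push <- FALSE
  st <- base$state
  if (wait > 0)
    st <- bd_run(st, wait, record_every = 0, control = ctrl_cyto)$state
  meas <- bd_run(st, measure, record_every = record_every,
                 control = ctrl_cyto)
  if (nrow(meas$state$pos) == 0)
    stop("network emptied before the cytochalasin measurement window")
  v1 <- mean_retrograde_speed(meas$frames)
  list(ratio = v1 / v0, v_retro = v0, v_retro_cytoD = v1, state = meas$state)
}

#' Bead-density histogram along x
#'
#' Bundling diagnostic: beads within a y band are binned by x. A bundled
#' (microspike-like) network concentrates density into few, narrow peaks; the
#' normalized coefficient of variation across bins increases with bundling.
#'
#' @param state a `network_state`
#' @param breaks x bin edges (um)
#' @param y_range y band to include (um)
#' @return data.frame of bin centers, counts, plus the `cv` attribute
#' @export
x_density_histogram <- function(state, breaks, y_range = c(0, Inf)) {
  sel <- state$pos[, 2] >= y_range[1] & state$pos[, 2] <= y_range[2]
  h <- hist(state$pos[sel, 1], breaks = breaks, plot = FALSE)
  out <- data.frame(x = h$mids, count = h$counts)
  attr(out, "cv") <- stats::sd(h$counts) / max(mean(h$counts), 1e-12)
  out
}

#' Nematic order of segment orientations
#'
#' 2D nematic order parameter of bond orientations (xy projection) within a
#' y band: \eqn{S = \sqrt{\langle\cos 2\phi\rangle^2 +
#' \langle\sin 2\phi\rangle^2}}; 0 for isotropic, 1 for perfectly aligned.
#'
#' @param state a `network_state`
#' @param y_range y band (um)
#' @return order parameter in `[0, 1]` (NA when no bonds in band)
#' @export
nematic_order <- function(state, y_range = c(-Inf, Inf)) {
  p <- state$params
  c2 <- s2 <- n <- 0
  for (b in state$fil_beads) {
    if (length(b) < 2) next
    for (k in seq_len(length(b) - 1)) {
      mid_y <- (state$pos[b[k], 2] + state$pos[b[k + 1], 2]) / 2
      if (mid_y < y_range[1] || mid_y > y_range[2]) next
      d <- min_image_disp(state$pos[b[k + 1], ], state$pos[b[k], ], p)
      phi <- atan2(d[2], d[1])
      c2 <- c2 + cos(2 * phi); s2 <- s2 + sin(2 * phi); n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  sqrt((c2 / n)^2 + (s2 / n)^2)
}

#' Rear-adhesion (transverse arc) scenario
#'
#' Places the focal adhesion deep in the lamellipodium (front edge at
#' `fa_y_start`, default 2.375 um) with a strong clutch (`kappa_FA` 250) and
#' sweeps the dynamic-crosslinker concentration, optionally replacing
#' permanent crosslinkers with long-lived ones (finite mean lifetime).
#' Records density profiles and bundling diagnostics.
#'
#' @param C_dynamic_values concentrations to sweep (uM)
#' @param longlived_lifetime mean lifetime of the "permanent" links (s), or
#'   `NA` for truly permanent
#' @param params base parameters (defaults to the desk profile with arc
#'   placement)
#' @param equil_time,measure_time,record_every run durations (s)
#' @return list per concentration: density profile, x histogram in front of
#'   the adhesion, nematic order, peak density location, final state
#' @export
arc_scenario <- function(C_dynamic_values = c(1, 10, 30),
                         longlived_lifetime = NA,
                         params = NULL,
                         equil_time = 12, measure_time = 6,
                         record_every = 1) {
  if (is.null(params))
    params <- desk_profile(kappa_FA = 250, fa_y_start = 2.375,
                           pull_mode = "uniform")$params
  params$longlived_lifetime <- longlived_lifetime
  out <- list()
  for (cd in C_dynamic_values) {
    p <- params
    p$C_dynamic <- cd
    state <- new_network_state(p)
    st <- bd_run(state, equil_time, record_every = 0)$state
    run <- bd_run(st, measure_time, record_every = record_every)
    fin <- run$state
    ybreaks <- seq(0, max(4, max(fin$pos[, 2], 0)) + 0.5, by = 0.25)
    dens <- density_profile(fin, ybreaks)
    band <- c(p$fa_y_start - 1, p$fa_y_start)
    out[[as.character(cd)]] <- list(
      C_dynamic = cd,
      density = dens,
      peak_y = dens$y[which.max(dens$density)],
      x_hist = x_density_histogram(fin, seq(0, p$box_width, by = 0.1), band),
      order = nematic_order(fin, band),
      state = fin)
  }
  out
}

#' Microspike (vertical filament bundle) scenario
#'
#' As [arc_scenario()] at fixed `C_dynamic`, but half of the inserted
#' filaments are vertical (axis along y); the pointed end is placed either
#' 35 nm from an existing filament (`near_existing`) or at a uniformly random
#' x (`random_x`). Reports the x-density histogram of the network body
#' (bundles show as narrow peaks) and the final state.
#'
#' @param submode vertical-insertion placement mode
#' @param params base parameters
#' @param equil_time,measure_time,record_every run durations (s)
#' @return list with the x histogram, its coefficient of variation, nematic
#'   order and final state
#' @export
microspike_scenario <- function(submode = c("near_existing", "random_x"),
                                params = NULL,
                                equil_time = 12, measure_time = 6,
                                record_every = 1) {
  submode <- match.arg(submode)
  if (is.null(params))
    params <- desk_profile(kappa_FA = 250, fa_y_start = 2.375,
                           C_dynamic = 10, pull_mode = "uniform")$params
  mode <- if (submode == "near_existing") "microspike_near"
          else "microspike_random"
  ctrl <- run_control(spawn_mode = mode)
  state <- new_network_state(params)
  st <- bd_run(state, equil_time, record_every = 0, control = ctrl)$state
  run <- bd_run(st, measure_time, record_every = record_every, control = ctrl)
  fin <- run$state
  xh <- x_density_histogram(fin, seq(0, params$box_width, by = 0.05),
                            c(0.5, Inf))
  list(x_hist = xh, cv = attr(xh, "cv"),
       order = nematic_order(fin, c(0.5, Inf)), state = fin)
}

# assemble a network_state from explicit chains and crosslinks
# chains: list of list(pos = matrix, taus = numeric)
# xl: matrix (a, b, type, tau) over the concatenated bead indexing
assemble_state <- function(params, chains, xl = NULL, branches = NULL) {
  s <- new_network_state(params)
  for (ch in chains) {
    n0 <- nrow(s$pos)
    nb <- nrow(ch$pos)
    pos <- ch$pos
    colnames(pos) <- c("x", "y", "z")
    s$pos <- rbind(s$pos, pos)
    s$uid <- c(s$uid, s$next_uid + seq_len(nb) - 1)
    s$next_uid <- s$next_uid + nb
    s$birth <- c(s$birth, rep(s$t, nb))
    s$bound <- c(s$bound, rep(0L, nb))
    s$wrapn <- c(s$wrapn, rep(0L, nb))
    s$fil_beads <- c(s$fil_beads, list(n0 + seq_len(nb)))
    s$fil_taus <- c(s$fil_taus, list(as.numeric(ch$taus)))
    s$fil_ids <- c(s$fil_ids, s$next_fil_id)
    s$next_fil_id <- s$next_fil_id + 1L
  }
  if (!is.null(xl) && nrow(xl)) {
    colnames(xl) <- c("a", "b", "type", "tau")
    s$xl <- xl
  }
  if (!is.null(branches) && nrow(branches)) {
    colnames(branches) <- c("i", "j", "k")
    s$branches <- branches
  }
  s
}

#' Extract a widened, open-boundary patch for mechanical testing
#'
#' Freezes network remodeling, equilibrates without external pushing/pulling
#' forces, tiles the periodic box once along x (reconnecting the periodic
#' bonds across the new interface), severs the remaining periodic seam and
#' cuts the result to `x` in `[-w/2, 3w/2]` and `y` in `y_cut`, removing
#' outside beads and any bond or crosslink to them. Actin-bond severing
#' times are set to infinity (turnover stays frozen during testing); dynamic
#' crosslinks keep their lifetimes so they may unbind and rebind during the
#' test. Disconnected fragments created by the cut are counted.
#'
#' @param state a steady-state `network_state` (periodic)
#' @param equil_time equilibration time without external forces (s)
#' @param y_cut y range to keep (um)
#' @return list with the open-boundary `state` (periodic = FALSE) and
#'   `n_fragments`, the number of connected components
#' @export
extract_mechanical_patch <- function(state, equil_time = 50,
                                     y_cut = c(-0.5, 3.5)) {
  p <- state$params
  ctrl <- run_control(push = FALSE, motor = FALSE, spawn = FALSE,
                      expiry = FALSE, dynamic = FALSE, fa_kinetics = FALSE)
  if (equil_time > 0)
    state <- bd_run(state, equil_time, record_every = 0, control = ctrl)$state
  w <- p$box_width
  # unwrap every chain into continuous coordinates, base bead in [0, w)
  chains <- lapply(seq_along(state$fil_beads), function(f) {
    b <- state$fil_beads[[f]]
    pos <- state$pos[b, , drop = FALSE]
    if (nrow(pos) > 1) {
      for (k in 2:nrow(pos)) {
        dx <- pos[k, 1] - pos[k - 1, 1]
        pos[k, 1] <- pos[k - 1, 1] + (dx - w * round(dx / w))
      }
    }
    list(pos = pos, taus = rep(Inf, max(nrow(pos) - 1, 0)), beads = b)
  })
  # bead index maps old -> copy A / copy B position in the assembled state
  nbead <- nrow(state$pos)
  mapA <- integer(nbead); mapB <- integer(nbead)
  off <- 0L
  dup <- list()
  for (ch in chains) {
    nb <- nrow(ch$pos)
    mapA[ch$beads] <- off + seq_len(nb)
    off <- off + nb
    dup[[length(dup) + 1]] <- ch
  }
  for (ch in chains) {
    nb <- nrow(ch$pos)
    posB <- ch$pos
    posB[, 1] <- posB[, 1] + w
    mapB[ch$beads] <- off + seq_len(nb)
    off <- off + nb
    dup[[length(dup) + 1]] <- list(pos = posB, taus = ch$taus)
  }
  xA <- numeric(nbead)
  for (ch in chains) xA[ch$beads] <- ch$pos[, 1]
  # crosslinks: a non-wrapping link duplicates to both copies; a link that
  # wrapped the original box reconnects once across the new interface
  xl <- NULL
  if (nrow(state$xl)) {
    rows <- list()
    for (q in seq_len(nrow(state$xl))) {
      a <- state$xl[q, 1]; b <- state$xl[q, 2]
      ty <- state$xl[q, 3]; tau <- state$xl[q, 4]
      if (ty == 3 && is.finite(tau)) tau <- tau else tau <- Inf
      dxu <- xA[b] - xA[a]
      if (abs(dxu) <= w / 2) {
        rows[[length(rows) + 1]] <- c(mapA[a], mapA[b], ty, tau)
        rows[[length(rows) + 1]] <- c(mapB[a], mapB[b], ty, tau)
      } else if (dxu < -w / 2) {
        rows[[length(rows) + 1]] <- c(mapA[a], mapB[b], ty, tau)
      } else {
        rows[[length(rows) + 1]] <- c(mapB[a], mapA[b], ty, tau)
      }
    }
    xl <- do.call(rbind, rows)
  }
  p2 <- p
  p2$box_width <- 2 * w
  p2$periodic <- FALSE
  p2$fa_on <- FALSE
  p2 <- resolve_fa_geometry(p2)
  patch <- assemble_state(p2, dup, xl)
  # shift so the patch occupies x ~ [-w/2, 3w/2], then cut
  patch$pos[, 1] <- patch$pos[, 1] - w / 2
  keep <- patch$pos[, 1] >= -w / 2 & patch$pos[, 1] <= 3 * w / 2 &
          patch$pos[, 2] >= y_cut[1] & patch$pos[, 2] <= y_cut[2]
  patch <- cut_beads(patch, keep)
  n_frag <- count_components(patch)
  list(state = patch, n_fragments = n_frag)
}

# remove beads (keep = logical), splitting chains and dropping crosslinks
cut_beads <- function(state, keep) {
  remap <- cumsum(keep)
  remap[!keep] <- NA
  chains <- list()
  for (f in seq_along(state$fil_beads)) {
    b <- state$fil_beads[[f]]
    tv <- state$fil_taus[[f]]
    runs <- rle(keep[b])
    pos0 <- cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      lo <- pos0[r]; hi <- pos0[r + 1] - 1
      if (hi - lo + 1 < 2) next
      chains[[length(chains) + 1]] <- list(
        old = b[lo:hi], taus = tv[lo:(hi - 1)])
    }
  }
  xl <- state$xl
  if (nrow(xl)) {
    ok <- keep[xl[, 1]] & keep[xl[, 2]]
    xl <- xl[ok, , drop = FALSE]
  }
  br <- state$branches
  if (nrow(br)) {
    ok <- keep[br[, 1]] & keep[br[, 2]] & keep[br[, 3]]
    br <- br[ok, , drop = FALSE]
  }
  # beads kept but in no chain (isolated after cutting) are dropped too
  inchain <- logical(nrow(state$pos))
  for (ch in chains) inchain[ch$old] <- TRUE
  keep2 <- keep & inchain
  remap <- cumsum(keep2)
  remap[!keep2] <- NA
  if (nrow(xl)) {
    ok <- !is.na(remap[xl[, 1]]) & !is.na(remap[xl[, 2]])
    xl <- xl[ok, , drop = FALSE]
    xl[, 1] <- remap[xl[, 1]]
    xl[, 2] <- remap[xl[, 2]]
  }
  if (nrow(br)) {
    ok <- !is.na(remap[br[, 1]]) & !is.na(remap[br[, 2]]) &
          !is.na(remap[br[, 3]])
    br <- br[ok, , drop = FALSE]
    for (c3 in 1:3) br[, c3] <- remap[br[, c3]]
  }
  out <- new_network_state(state$params)
  out$pos <- state$pos[keep2, , drop = FALSE]
  n <- nrow(out$pos)
  out$uid <- state$uid[keep2]
  out$birth <- state$birth[keep2]
  out$bound <- state$bound[keep2]
  out$wrapn <- rep(0L, n)
  out$next_uid <- state$next_uid
  out$next_fil_id <- state$next_fil_id
  for (ch in chains) {
    out$fil_beads[[length(out$fil_beads) + 1]] <-
      as.integer(remap[ch$old])
    out$fil_taus[[length(out$fil_taus) + 1]] <- as.numeric(ch$taus)
    out$fil_ids <- c(out$fil_ids, out$next_fil_id)
    out$next_fil_id <- out$next_fil_id + 1L
  }
  if (!is.null(xl) && nrow(xl)) out$xl <- xl
  if (!is.null(br) && nrow(br)) out$branches <- br
  out$t <- state$t
  out
}

# connected components over bonds + crosslinks
count_components <- function(state) {
  n <- nrow(state$pos)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  join <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (b in state$fil_beads)
    if (length(b) > 1)
      for (k in seq_len(length(b) - 1)) join(b[k], b[k + 1])
  if (nrow(state$xl))
    for (q in seq_len(nrow(state$xl))) join(state$xl[q, 1], state$xl[q, 2])
  length(unique(vapply(seq_len(n), function(i) as.integer(find(i)),
                       integer(1))))
}

#' Generate a synthetic crosslinked lattice patch
#'
#' A small, fully synthetic stand-in for the extracted steady-state patch:
#' a crossed grid of straight filaments along x (at one z level) and along y
#' (at another, 0.04 um apart, inside the crosslinker capture window), with a
#' permanent crosslink at every near-intersection. Intended for desk-scale
#' mechanical tests where the full-scale extracted patch is too costly.
#'
#' @param params parameter list (non-periodic recommended)
#' @param width,height patch extent in x and y (um)
#' @param spacing distance between parallel filaments (um)
#' @return a `network_state`, non-periodic
#' @export
build_synthetic_patch <- function(params = NULL, width = 1.6, height = 1.6,
                                  spacing = 0.2) {
  if (is.null(params))
    params <- default_parameters(periodic = FALSE, fa_on = FALSE,
                                 box_width = width + 1)
  params$periodic <- FALSE
  params$fa_on <- FALSE
  s <- new_network_state(params)
  l0 <- params$l0
  zx <- params$box_height / 2 - 0.02
  zy <- zx + 0.04
  nxf <- floor(height / spacing) + 1
  nyf <- floor(width / spacing) + 1
  for (q in seq_len(nxf))  # filaments along x
    s <- add_filament(s, c(0, (q - 1) * spacing, zx), dir = c(1, 0, 0),
                      n_beads = round(width / l0) + 1)
  for (q in seq_len(nyf))  # filaments along y
    s <- add_filament(s, c((q - 1) * spacing, 0, zy), dir = c(0, 1, 0),
                      n_beads = round(height / l0) + 1)
  # crosslink every near-intersection (vertical separation 0.04 um)
  nx_beads <- nxf * (round(width / l0) + 1)
  for (fx in seq_len(nxf)) {
    bx <- s$fil_beads[[fx]]
    for (fy in seq_len(nyf)) {
      by <- s$fil_beads[[nxf + fy]]
      xi <- bx[which.min(abs(s$pos[bx, 1] - (fy - 1) * spacing))]
      yi <- by[which.min(abs(s$pos[by, 2] - (fx - 1) * spacing))]
      s <- add_crosslink(s, xi, yi, "permanent", Inf)
    }
  }
  s
}

#' Uniaxial extension or compression test
#'
#' Beads within `clamp_depth` of the two y faces of the patch are clamped
#' and translated apart (extension) or together (compression) at a relative
#' speed of `strain_rate * gauge`, split symmetrically between the two
#' clamps, up to `strain_max` engineering strain on the gauge length.
#' Thermal forces and excluded volume stay on; dynamic crosslinks may expire
#' and re-form. The tensile stress
#' \eqn{\sigma_T = \sigma_{yy} - (\sigma_{xx} + \sigma_{zz})/2} is sampled
#' from the virial over non-clamped beads at each strain sample; compression
#' curves report \eqn{-\sigma_T}.
#'
#' @param patch an open-boundary `network_state` (from
#'   [extract_mechanical_patch()] or [build_synthetic_patch()])
#' @param mode "extension" or "compression"
#' @param strain_rate engineering strain rate (1/s)
#' @param strain_max final strain
#' @param n_samples number of strain samples
#' @param clamp_depth clamp depth from each face (um)
#' @param top_wall keep the z = box_height wall (set FALSE to allow buckling)
#' @param y_range gauge faces (um); defaults to the occupied y extent
#' @param volume reference volume for the virial (um^3); defaults to the
#'   initial bounding volume of the gauge region
#' @return data.frame of class `stress_strain`: strain, reported stress (Pa),
#'   with the test mode and wall flag as attributes
#' @export
uniaxial_test <- function(patch, mode = c("extension", "compression"),
                          strain_rate = 0.05, strain_max = 0.5,
                          n_samples = 11, clamp_depth = 0.25,
                          top_wall = TRUE, y_range = NULL, volume = NULL) {
  mode <- match.arg(mode)
  p <- patch$params
  p$top_wall <- top_wall
  patch$params <- p
  if (is.null(y_range))
    y_range <- range(patch$pos[, 2])
  gauge <- diff(y_range)
  lo <- which(patch$pos[, 2] <= y_range[1] + clamp_depth)
  hi <- which(patch$pos[, 2] >= y_range[2] - clamp_depth)
  if (!length(lo) || !length(hi)) stop("empty clamp set")
  sgn <- if (mode == "extension") 1 else -1
  v <- strain_rate * gauge              # relative clamp speed (um/s)
  clamp <- list(idx = c(lo, hi),
                vy = c(rep(-sgn * v / 2, length(lo)),
                       rep(sgn * v / 2, length(hi))))
  if (is.null(volume)) {
    xr <- range(patch$pos[, 1])
    volume <- diff(xr) * gauge * p$box_height
  }
  ctrl <- run_control(push = FALSE, motor = FALSE, spawn = FALSE,
                      expiry = TRUE, dynamic = TRUE, fa_kinetics = FALSE)
  strains <- seq(0, strain_max, length.out = n_samples)
  stress <- numeric(n_samples)
  vir0 <- virial_stress(patch, volume, exclude = clamp$idx)
  stress[1] <- sgn * vir0$sigma_T
  st <- patch
  for (q in 2:n_samples) {
    dt_seg <- (strains[q] - strains[q - 1]) / strain_rate
    st <- bd_run(st, dt_seg, record_every = 0, control = ctrl,
                 clamp = clamp)$state
    vol_q <- volume * (1 + sgn * strains[q])
    vir <- virial_stress(st, vol_q, exclude = clamp$idx)
    stress[q] <- sgn * vir$sigma_T
  }
  out <- data.frame(strain = strains, stress = stress)
  attr(out, "mode") <- mode
  attr(out, "top_wall") <- top_wall
  class(out) <- c("stress_strain", "data.frame")
  out
}

#' Elastic modulus from a stress-strain curve
#'
#' The secant modulus: reported stress divided by strain, at the requested
#' strain (linear interpolation between samples).
#'
#' @param curve a [uniaxial_test()] result
#' @param strain evaluation strain (default 0.2)
#' @return modulus (Pa)
#' @export
modulus_at_strain <- function(curve, strain = 0.2) {
  if (strain < min(curve$strain) || strain > max(curve$strain))
    stop("curve does not cover the requested strain")
  s <- stats::approx(curve$strain, curve$stress, xout = strain)$y
  s / strain
}
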