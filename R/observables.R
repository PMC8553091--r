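frame_df <- function(frame) {
  data.frame(uid = frame$pos[, 1], x = frame$pos[, 2], y = frame$pos[, 3],
             z = frame$pos[, 4], t = frame$t)
}

#' Retrograde flow speed versus distance from the leading edge
#'
#' Bead velocities dy/dt are estimated by finite differences between
#' consecutive recorded frames (beads matched by persistent id; positive
#' values are retrograde, towards +y) and averaged in bins of y.
#'
#' @param frames list of frames from a [bd_run()]
#' @param breaks y bin edges (um)
#' @return data.frame with bin centers, mean speed (um/s), and sample counts;
#'   empty bins carry `NA`
#' @export
retrograde_flow_profile <- function(frames, breaks) {
  if (length(frames) < 2) stop("need at least two frames")
  ys <- numeric(0); vs <- numeric(0)
  for (q in seq_len(length(frames) - 1)) {
    a <- frame_df(frames[[q]]); b <- frame_df(frames[[q + 1]])
    dtq <- b$t[1] - a$t[1]
    m <- match(a$uid, b$uid)
    keep <- !is.na(m)
    ys <- c(ys, a$y[keep])
    vs <- c(vs, (b$y[m[keep]] - a$y[keep]) / dtq)
  }
  bin <- cut(ys, breaks, include.lowest = TRUE)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  v <- tapply(vs, bin, mean)
  n <- tapply(vs, bin, length)
  data.frame(y = mid, speed = as.numeric(v),
             n = ifelse(is.na(n), 0L, as.integer(n)))
}

#' Mean retrograde flow speed over all beads
#'
#' All-bead average of dy/dt across consecutive recorded frames.
#' @param frames list of frames from a [bd_run()]
#' @return mean speed (um/s)
#' @export
mean_retrograde_speed <- function(frames) {
  if (length(frames) < 2) stop("need at least two frames")
  tot <- 0; n <- 0
  for (q in seq_len(length(frames) - 1)) {
    a <- frame_df(frames[[q]]); b <- frame_df(frames[[q + 1]])
    dtq <- b$t[1] - a$t[1]
    m <- match(a$uid, b$uid)
    keep <- !is.na(m)
    tot <- tot + sum((b$y[m[keep]] - a$y[keep]) / dtq)
    n <- n + sum(keep)
  }
  tot / n
}

# per-bead monomer attribution: each bond carries monomers_per_segment
# monomers, split half to each endpoint bead
bead_monomers <- function(state) {
  w <- numeric(nrow(state$pos))
  half <- state$params$monomers_per_segment / 2
  for (b in state$fil_beads) {
    if (length(b) < 2) next
    w[b[-length(b)]] <- w[b[-length(b)]] + half
    w[b[-1]] <- w[b[-1]] + half
  }
  w
}

#' Actin density profile along y
#'
#' Monomer counts attributed to beads are binned by y and converted to uM
#' using the bin volume `box_width * bin_height * box_height`. Multiple
#' states (a time window) may be supplied; the profile is then time-averaged.
#'
#' @param states a `network_state` or list of them
#' @param breaks y bin edges (um)
#' @return data.frame with bin centers and density (uM)
#' @export
density_profile <- function(states, breaks) {
  if (inherits(states, "network_state")) states <- list(states)
  p <- states[[1]]$params
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  vol <- p$box_width * diff(breaks) * p$box_height
  acc <- numeric(length(mid))
  for (s in states) {
    w <- bead_monomers(s)
    bin <- cut(s$pos[, 2], breaks, include.lowest = TRUE)
    cnt <- tapply(w, bin, sum)
    cnt[is.na(cnt)] <- 0
    acc <- acc + as.numeric(cnt)
  }
  data.frame(y = mid,
             density = monomer_count_to_micromolar(acc / length(states), vol))
}

bond_tensions <- function(state) {
  p <- state$params
  out <- lapply(state$fil_beads, function(b) {
    if (length(b) < 2) return(NULL)
    i <- b[-length(b)]; j <- b[-1]
    dx <- state$pos[j, 1] - state$pos[i, 1]
    dx <- dx - p$box_width * round(dx / p$box_width) * p$periodic
    dy <- state$pos[j, 2] - state$pos[i, 2]
    dz <- state$pos[j, 3] - state$pos[i, 3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    mx <- state$pos[i, 1] + dx / 2
    mx <- mx - p$box_width * floor(mx / p$box_width) * p$periodic
    data.frame(x = mx, y = state$pos[i, 2] + dy / 2,
               tension = p$k_actin * (p$l0 - d))
  })
  do.call(rbind, out)
}

#' Bond tension map on an xy grid
#'
#' Per-bond scalar `k_actin * (l0 - d)` (positive = compression, negative =
#' extension) averaged onto an xy grid at bond midpoints, over one or more
#' states (time and z averaging).
#'
#' @param states a `network_state` or list of them
#' @param xbreaks,ybreaks grid edges (um)
#' @return list with `x`, `y` (bin centers) and matrix `tension`
#'   (pN; rows = x bins), `count`
#' @export
bond_tension_map <- function(states, xbreaks, ybreaks) {
  if (inherits(states, "network_state")) states <- list(states)
  nx <- length(xbreaks) - 1; ny <- length(ybreaks) - 1
  sum_t <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (s in states) {
    td <- bond_tensions(s)
    if (is.null(td) || !nrow(td)) next
    ix <- findInterval(td$x, xbreaks, rightmost.closed = TRUE)
    iy <- findInterval(td$y, ybreaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    for (q in which(ok)) {
      sum_t[ix[q], iy[q]] <- sum_t[ix[q], iy[q]] + td$tension[q]
      cnt[ix[q], iy[q]] <- cnt[ix[q], iy[q]] + 1
    }
  }
  avg <- sum_t / cnt
  avg[cnt == 0] <- NA_real_
  list(x = (xbreaks[-1] + xbreaks[-(nx + 1)]) / 2,
       y = (ybreaks[-1] + ybreaks[-(ny + 1)]) / 2,
       tension = avg, count = cnt)
}

#' Filament bending-angle profile along y
#'
#' For every full-length filament (exactly `beads_per_filament` beads), the
#' angle between the two half-length chords (pointed bead to middle bead,
#' middle bead to barbed bead) is computed in degrees and binned by the
#' middle bead's y position. Severed fragments are skipped.
#'
#' @param states a `network_state` or list of them
#' @param breaks y bin edges (um)
#' @return data.frame with bin centers, mean angle, upper-quartile angle and
#'   counts
#' @export
bending_angle_profile <- function(states, breaks) {
  if (inherits(states, "network_state")) states <- list(states)
  p <- states[[1]]$params
  nb <- p$beads_per_filament
  midbead <- (nb + 1) %/% 2
  ys <- numeric(0); th <- numeric(0)
  for (s in states) {
    for (b in s$fil_beads) {
      if (length(b) != nb) next
      r0 <- s$pos[b[1], ]; rm <- s$pos[b[midbead], ]; r1 <- s$pos[b[nb], ]
      c1 <- min_image_disp(rm, r0, p)
      c2 <- min_image_disp(r1, rm, p)
      cth <- sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
      th <- c(th, acos(pmin(1, pmax(-1, cth))) * 180 / pi)
      ys <- c(ys, rm[2])
    }
  }
  bin <- cut(ys, breaks, include.lowest = TRUE)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(
    y = mid,
    mean_angle = as.numeric(tapply(th, bin, mean)),
    q75_angle = as.numeric(tapply(th, bin, stats::quantile, probs = 0.75)),
    n = as.integer(ifelse(is.na(tapply(th, bin, length)), 0,
                          tapply(th, bin, length)))
  )
}

#' Time-averaged force balance of a run
#'
#' Averages the recorded per-frame channel totals (y components): pushing,
#' motor pulling, confinement, thermal, and the drag decomposition into
#' cytoplasmic fluid drag and focal-adhesion drag. Values are reported per um
#' of leading edge (divided by `box_width`) and per bead. The residual
#' (external forces minus total drag) is a closure check; it is identically
#' zero per step up to the recorded thermal realization.
#'
#' @param run a [bd_run()] result with recorded frames
#' @return data.frame with one row per channel
#' @export
force_balance_summary <- function(run) {
  cs <- run$channel_sums
  if (!length(cs)) stop("run has no recorded channel sums")
  p <- run$state$params
  ysum <- sapply(cs, function(m) m[, 2])   # rows: channels, cols: frames
  mean_y <- rowMeans(ysum)
  nb <- mean(vapply(run$frames, function(f) f$n_beads, numeric(1)))
  chans <- c("leading", "motor", "confine", "thermal", "fluid_drag", "fa_drag")
  drag <- mean_y["fluid_drag"] + mean_y["fa_drag"]
  ext <- sum(mean_y[c("leading", "motor", "confine", "thermal")])
  data.frame(
    channel = c(chans, "residual"),
    force_y = c(mean_y[chans], ext - drag),
    per_um = c(mean_y[chans], ext - drag) / p$box_width,
    per_bead = c(mean_y[chans], ext - drag) / nb,
    row.names = NULL
  )
}

#' Virial stress tensor of a network
#'
#' \eqn{\sigma_{ij} = -(1/V) \sum_{pairs} r_{ab,i} F_{ab,j}} over bond,
#' crosslink, excluded-volume and (pairwise-decomposed) bending and branch
#' interactions, with tension positive; pairs touching excluded beads (e.g.
#' clamped beads in a mechanical test) are skipped. Output in Pa
#' (1 pN/um^2 = 1 Pa). The tensile stress is
#' \eqn{\sigma_T = \sigma_{yy} - (\sigma_{xx} + \sigma_{zz})/2}.
#'
#' @param state a `network_state`
#' @param volume reference volume (um^3)
#' @param exclude bead indices to exclude (clamped beads)
#' @return list with the 3x3 `sigma` (Pa) and scalar `sigma_T`
#' @export
virial_stress <- function(state, volume, exclude = integer(0)) {
  cpp_virial(st_core(state), state$params, volume, as.integer(exclude))
}
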