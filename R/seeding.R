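## Particle seeding: populate flow trajectories and stationary tissue with
## volume-weighted spin packets. Each trajectory i carries particles spaced
## by the inlet distance dl_i, each representing the prism volume
## V_i = A_i * dl_i (A_i its Voronoi inlet area); fresh particles are
## injected at the inlet every dt_i = dl_i / v_i(inlet) so the vessel stays
## filled. The per-particle volume is constant along the trajectory: in a
## narrowing the spacing grows exactly as the cross-section shrinks.

#' Tissue (spin) properties
#'
#' Relaxation times, relative proton density and chemical-shift offset of
#' one tissue component.
#'
#' @param T1 longitudinal relaxation time, ms.
#' @param T2 transverse relaxation time, ms; a warning is issued if
#'   `T2 > T1` (unphysical).
#' @param rho relative proton density (water = 1).
#' @param domega chemical-shift / off-resonance angular frequency, rad/ms.
#' @param name label used in reports.
#' @param ... extra metadata (e.g. density, viscosity) carried along.
#' @return an object of class `tissue_properties`.
#' @export
tissue_properties <- function(T1, T2, rho = 1, domega = 0, name = "tissue", ...) {
  if (T1 <= 0 || T2 <= 0) stopf("T1 and T2 must be positive")
  if (rho < 0) stopf("proton density must be >= 0")
  if (T2 > T1) warnf("T2 (%g ms) exceeds T1 (%g ms): unphysical combination", T2, T1)
  structure(list(T1 = T1, T2 = T2, rho = rho, domega = domega, name = name,
                 meta = list(...)),
            class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<tissue '%s': T1 = %g ms, T2 = %g ms, rho = %g, domega = %g rad/ms>\n",
              x$name, x$T1, x$T2, x$rho, x$domega))
  invisible(x)
}

#' Per-trajectory seeding parameters
#'
#' Computes, for every trajectory of a bundle, the inlet Voronoi area
#' `A_i`, inlet particle spacing `dl_i`, injection interval
#' `dt_i = dl_i / v_i(0)` and particle volume `V_i = A_i * dl_i`.
#'
#' @param trajectories a trajectory bundle from `trace_trajectories()` /
#'   [integrate_trajectory()].
#' @param target_linear_density particles per millimetre of vessel length
#'   along each trajectory (default 3/mm, i.e. `dl = 1/3` mm).
#' @param inlet_radius inlet disc radius (mm); defaults to the bundle's.
#' @param areas optional pre-computed Voronoi areas (mm^2).
#' @return a data.frame with one row per trajectory: `trajectory_id`,
#'   `area`, `dl`, `dt_inj`, `volume`, `v_inlet`, `duration`.
#' @export
seed_trajectories <- function(trajectories, target_linear_density = 3,
                              inlet_radius = NULL, areas = NULL) {
  if (target_linear_density <= 0) stopf("target_linear_density must be > 0")
  inlet_radius <- inlet_radius %||% attr(trajectories, "inlet_radius")
  if (is.null(areas)) {
    if (is.null(inlet_radius))
      stopf("supply inlet_radius (or areas) to tessellate the inlet")
    ip <- t(vapply(trajectories, function(tr) tr$inlet_point, numeric(2)))
    areas <- voronoi_inlet_areas(ip, inlet_radius)
  }
  v0 <- vapply(trajectories, function(tr) tr$speed[1L], numeric(1))
  if (any(v0 <= 0)) stopf("zero inlet speed on trajectory")
  dl <- 1 / target_linear_density
  data.frame(
    trajectory_id = vapply(trajectories, function(tr) tr$id, numeric(1)),
    area = areas,
    dl = dl,
    dt_inj = dl / v0,
    volume = areas * dl,
    v_inlet = v0,
    duration = vapply(trajectories, function(tr) tr$duration, numeric(1))
  )
}

## number of particles that fit on a trajectory at injection interval dt
n_particles_on <- function(duration, dt_inj) {
  pmax(0L, as.integer(floor(duration / dt_inj + 1e-6)))
}

#' Populate trajectories with particles
#'
#' Fills every trajectory with particles covering the whole vessel at time
#' `t0`. Particle k on trajectory i sits where the fluid thread was
#' `k * dt_i` after entering the inlet, i.e. at inlet spacing `dl_i`
#' stretched by the local speed. All spins start at thermal equilibrium,
#' `M = (0, 0, rho)`.
#'
#' @param seedings data.frame from [seed_trajectories()].
#' @param trajectories the matching trajectory bundle.
#' @param tissue a [tissue_properties()] object for the flowing fluid.
#' @param t0 simulation time (ms) at which the snapshot is taken.
#' @return an object of class `particle_set`.
#' @export
populate <- function(seedings, trajectories, tissue, t0 = 0) {
  stopifnot(inherits(tissue, "tissue_properties"))
  counts <- n_particles_on(seedings$duration, seedings$dt_inj)
  traj <- rep(seq_len(nrow(seedings)), counts)
  k <- sequence(counts) - 1L
  tshift <- k * seedings$dt_inj[traj]
  n <- length(traj)
  ps <- list(
    label = seq_len(n),
    traj = traj,
    tshift = tshift,
    volume = seedings$volume[traj],
    tissue_id = rep(1L, n),
    M = cbind(Mx = numeric(n), My = numeric(n), Mz = rep(tissue$rho, n)),
    pos0 = NULL,
    tissues = list(tissue),
    bundle = trajectories,
    seedings = seedings,
    t0 = t0,
    next_birth = seedings$dt_inj,   # first injection after t0
    n_label = n,
    stationary = FALSE
  )
  class(ps) <- "particle_set"
  ps
}

#' Positions of the particles of a set at time t
#'
#' Moving particles are interpolated along their trajectories; stationary
#' ones return their fixed coordinates. Expired / unborn particles give
#' `NA` rows.
#' @param particles a `particle_set`.
#' @param t simulation time (ms).
#' @return `n x 3` matrix of positions (mm).
#' @export
particle_positions <- function(particles, t) {
  if (particles$stationary) return(particles$pos0)
  n <- length(particles$label)
  pos <- matrix(NA_real_, n, 3)
  tt <- (t - particles$t0) + particles$tshift
  for (i in seq_along(particles$bundle)) {
    tr <- particles$bundle[[i]]
    sel <- particles$traj == i & tt >= -1e-9 & tt <= tr$duration + 1e-9
    if (any(sel)) pos[sel, ] <- interpolate_position(tr, tt[sel])
  }
  tf <- attr(particles, "transform")
  if (!is.null(tf)) {
    pos[, 1] <- pos[, 1] + tf$origin[1]
    pos[, 2] <- pos[, 2] + tf$origin[2]
    pos[, 3] <- pos[, 3] * tf$zsign + tf$origin[3]
  }
  pos
}

#' Which particles are alive at time t
#' @inheritParams particle_positions
#' @return logical vector.
#' @export
particles_alive <- function(particles, t) {
  if (particles$stationary) return(rep(TRUE, length(particles$label)))
  tt <- (t - particles$t0) + particles$tshift
  dur <- vapply(particles$bundle, function(tr) tr$duration, numeric(1))
  tt >= -1e-9 & tt <= dur[particles$traj] + 1e-9
}

#' Retire out-flowed particles and inject fresh ones
#'
#' Advances the particle bookkeeping to time `t`: particles that passed the
#' outlet are removed and every trajectory injects a fresh particle each
#' `dt_i`, at thermal equilibrium (no transverse magnetization -- a fresh
#' spin has seen no RF pulse). Stationary sets are returned unchanged.
#'
#' @param particles a `particle_set`.
#' @param t simulation time (ms), `>= t0`.
#' @return the updated `particle_set`.
#' @export
replenish <- function(particles, t) {
  if (particles$stationary) return(particles)
  if (t < particles$t0 - 1e-9) stopf("cannot replenish backwards in time")
  sd <- particles$seedings
  dur <- sd$duration
  tt <- (t - particles$t0) + particles$tshift
  keep <- tt <= dur[particles$traj] + 1e-9
  rho <- particles$tissues[[1L]]$rho
  new_traj <- integer(0); new_tshift <- numeric(0)
  nb <- particles$next_birth
  for (i in seq_len(nrow(sd))) {
    while (nb[i] <= (t - particles$t0) + 1e-9) {
      new_traj <- c(new_traj, i)
      new_tshift <- c(new_tshift, -nb[i])
      nb[i] <- nb[i] + sd$dt_inj[i]
    }
  }
  n_new <- length(new_traj)
  out <- particles
  out$label <- c(particles$label[keep], particles$n_label + seq_len(n_new))
  out$traj <- c(particles$traj[keep], new_traj)
  out$tshift <- c(particles$tshift[keep], new_tshift)
  out$volume <- c(particles$volume[keep], sd$volume[new_traj])
  out$tissue_id <- c(particles$tissue_id[keep], rep(1L, n_new))
  out$M <- rbind(particles$M[keep, , drop = FALSE],
                 cbind(numeric(n_new), numeric(n_new), rep(rho, n_new)))
  out$next_birth <- nb
  out$n_label <- particles$n_label + n_new
  out
}

#' Stationary tissue particles
#'
#' Uniform random placement of fixed spin packets inside a box, excluding
#' vessel lumens. Each particle carries the volume `1 / density` so the
#' summed particle volume matches the tissue volume in expectation.
#'
#' @param region list `(lower, upper)`: opposite corners of the box (mm).
#' @param tissue a [tissue_properties()] object.
#' @param density particles per mm^3 (match the moving-particle density).
#' @param exclude optional list of channels (as in a phantom: each a list
#'   with `geometry` and `center = c(x, y)` placement) whose lumens are
#'   carved out.
#' @param seed RNG seed for reproducible placement.
#' @return a stationary `particle_set`.
#' @export
make_stationary_tissue <- function(region, tissue, density, exclude = NULL,
                                   seed = NULL) {
  stopifnot(inherits(tissue, "tissue_properties"))
  if (density <= 0) stopf("density must be > 0")
  lower <- region$lower; upper <- region$upper
  if (any(upper <= lower)) stopf("empty region")
  vol <- prod(upper - lower)
  pts <- with_seed(seed, {
    n <- stats::rpois(1, vol * density)
    matrix(stats::runif(3 * n, rep(lower, each = n), rep(upper, each = n)), n, 3)
  })
  if (!is.null(exclude) && nrow(pts) > 0) {
    inside <- rep(FALSE, nrow(pts))
    for (ch in exclude) {
      z0 <- ch$z0 %||% 0
      dirn <- ch$direction %||% 1
      local <- cbind(pts[, 1] - ch$center[1], pts[, 2] - ch$center[2],
                     (pts[, 3] - z0) * dirn)
      pr <- centerline_project(ch$geometry, local)
      ok <- pr$s >= 0 & pr$s <= ch$geometry$total_length
      inside <- inside | (ok & pr$r <= radius_at(ch$geometry, pr$s))
    }
    pts <- pts[!inside, , drop = FALSE]
  }
  n <- nrow(pts)
  ps <- list(
    label = seq_len(n),
    traj = rep(0L, n),
    tshift = rep(NA_real_, n),
    volume = rep(1 / density, n),
    tissue_id = rep(1L, n),
    M = cbind(Mx = numeric(n), My = numeric(n), Mz = rep(tissue$rho, n)),
    pos0 = pts,
    tissues = list(tissue),
    bundle = NULL,
    seedings = NULL,
    t0 = 0,
    next_birth = numeric(0),
    n_label = n,
    stationary = TRUE
  )
  class(ps) <- "particle_set"
  ps
}

#' @export
print.particle_set <- function(x, ...) {
  kind <- if (x$stationary) "stationary" else "flowing"
  cat(sprintf("<particle_set: %d %s particles, tissue '%s'>\n",
              length(x$label), kind, x$tissues[[1L]]$name))
  invisible(x)
}
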