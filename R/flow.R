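## Analytic laminar flow inside a tube_geometry. The velocity field is a
## quasi-one-dimensional Poiseuille profile: at arc length s the axial speed
## at fractional radius rt = r / R(s) is
##
##   v(s, rt) = v_max(s) * (1 - rt^2),     v_max(s) = 2 Q / (pi R(s)^2),
##
## so the volumetric flux through every cross-section equals the prescribed
## rate Q (continuity) and the speed is zero at the wall (no slip).
## Streamlines keep their fractional radius, which is the standard
## quasi-1D approximation for slowly varying lumens; the post-stenotic jet
## asymmetry of a real (turbulent) flow is deliberately not modelled.

#' Create a laminar flow field
#'
#' Attaches a volumetric flow rate to a tube geometry. Units: `flow_rate`
#' is in mm^3/ms, which is numerically identical to ml/s.
#'
#' @param geometry a [make_geometry()] object.
#' @param flow_rate volumetric rate Q in mm^3/ms (= ml/s).
#' @return an object of class `flow_field`.
#' @examples
#' f <- flow_field(make_geometry("straight", 8, 207), 2.5)
#' vmax_at(f, 0)  # ~0.0995 mm/ms = 99.5 mm/s
#' @export
flow_field <- function(geometry, flow_rate) {
  stopifnot(inherits(geometry, "tube_geometry"))
  if (!is.numeric(flow_rate) || flow_rate <= 0) stopf("flow_rate must be > 0")
  structure(list(geometry = geometry, flow_rate = flow_rate),
            class = "flow_field")
}

#' Peak (centerline) speed
#'
#' `v_max(s) = 2 Q / (pi R(s)^2)` in mm/ms, vectorised over `s`.
#' @param field a [flow_field()].
#' @param s arc length(s) in mm.
#' @export
vmax_at <- function(field, s) {
  2 * field$flow_rate / (pi * radius_at(field$geometry, s)^2)
}

#' Velocity vector at a point
#'
#' Evaluates the laminar velocity field at one or more 3D points (rows of
#' `points`, geometry-local coordinates in mm). The velocity is parallel to
#' the local centerline tangent with the parabolic no-slip profile.
#'
#' @param field a [flow_field()].
#' @param points numeric length-3 vector or `n x 3` matrix (mm).
#' @param strict error if any point lies outside the lumen (default); with
#'   `strict = FALSE` such rows are returned as `NA`.
#' @return `n x 3` matrix of velocities in mm/ms (a vector for one point).
#' @export
axial_velocity <- function(field, points, strict = TRUE) {
  one <- is.null(dim(points))
  pts <- rbind(points)
  pr <- centerline_project(field$geometry, pts)
  R <- radius_at(field$geometry, pr$s)
  out_of_domain <- pr$s < 0 | pr$s > field$geometry$total_length | pr$r > R * (1 + 1e-12)
  if (strict && any(out_of_domain))
    stopf("%d point(s) outside the lumen", sum(out_of_domain))
  rt2 <- pmin((pr$r / R)^2, 1)
  speed <- vmax_at(field, pr$s) * (1 - rt2)
  tg <- centerline_frame(field$geometry, pr$s)$tangent
  v <- tg * speed
  v[out_of_domain, ] <- NA_real_
  if (one) drop(v) else v
}

## Vectorised RK2 (midpoint) tracer for a set of inlet seeds. Each seed i
## starts at inlet offset (u_i, v_i) (mm on the inlet disc) and keeps its
## fractional radius rt_i = |(u,v)| / R(0). The arc-length ODE
## ds/dt = v_max(s) (1 - rt^2) is integrated with per-trajectory step dt.
trace_trajectories <- function(field, inlet_points, dt_flow = NULL,
                               n_steps = 65536L, step_length = 0.25) {
  geom <- field$geometry
  ip <- rbind(inlet_points)
  R0 <- radius_at(geom, 0)
  rr <- sqrt(ip[, 1]^2 + ip[, 2]^2)
  if (any(rr >= R0)) stopf("inlet point(s) outside the inlet disc")
  rt2 <- (rr / R0)^2
  v0 <- vmax_at(field, 0) * (1 - rt2)
  if (any(v0 <= 0)) stopf("inlet speed is zero on the wall; seed strictly inside")
  m <- nrow(ip)
  dt <- if (is.null(dt_flow)) step_length / v0 else rep_len(dt_flow, m)
  L <- geom$total_length
  s <- numeric(m)
  live <- rep(TRUE, m)
  ## record s per step in a growing matrix (steps x m)
  alloc <- min(n_steps, 4096L) + 1L
  hist <- matrix(NA_real_, alloc, m)
  hist[1L, ] <- 0
  k <- 1L
  while (any(live) && k <= n_steps) {
    if (k + 1L > nrow(hist)) {
      hist <- rbind(hist, matrix(NA_real_, min(nrow(hist), n_steps + 1L - nrow(hist)), m))
    }
    sl <- s[live]; dtl <- dt[live]
    g1 <- vmax_at(field, pmin(sl, L)) * (1 - rt2[live])
    smid <- sl + 0.5 * dtl * g1
    g2 <- vmax_at(field, pmin(smid, L)) * (1 - rt2[live])
    s[live] <- sl + dtl * g2
    k <- k + 1L
    hist[k, live] <- pmin(s[live], L)
    live[live] <- s[live] < L
  }
  out <- vector("list", m)
  for (i in seq_len(m)) {
    si <- hist[, i]
    si <- si[!is.na(si)]
    ## trim anything past the outlet to the outlet sample
    if (any(si >= L)) si <- c(si[si < L], L)
    n <- length(si)
    fr <- centerline_frame(geom, si)
    scale <- radius_at(geom, si) / R0
    pos <- fr$p + fr$n1 * (ip[i, 1] * scale) + fr$n2 * (ip[i, 2] * scale)
    speed <- vmax_at(field, si) * (1 - rt2[i])
    tr <- list(id = i, t = (seq_len(n) - 1) * dt[i], s = si,
               pos = pos, speed = speed, dt_flow = dt[i],
               inlet_point = ip[i, ], r_frac = sqrt(rt2[i]),
               duration = (n - 1) * dt[i])
    class(tr) <- "trajectory"
    out[[i]] <- tr
  }
  class(out) <- "trajectory_bundle"
  attr(out, "inlet_radius") <- R0
  attr(out, "field") <- field
  out
}

#' Integrate one particle trajectory
#'
#' Traces a fluid thread from an inlet seed point to the outlet with the
#' explicit midpoint (RK2) scheme on the arc-length equation
#' `ds/dt = v_max(s) (1 - rt^2)`. Samples are uniformly spaced in time by
#' `dt_flow`; the final sample is clamped to the outlet.
#'
#' @param field a [flow_field()].
#' @param inlet_point length-2 offset (mm) on the inlet disc.
#' @param dt_flow flow-simulation time step in ms (default 1).
#' @param n_steps maximum number of steps before giving up.
#' @return an object of class `trajectory` with elements `t` (ms), `pos`
#'   (n x 3 mm), `speed` (mm/ms), `s` (arc length), `dt_flow`, `duration`.
#' @export
integrate_trajectory <- function(field, inlet_point, dt_flow = 1,
                                 n_steps = 65536L) {
  trace_trajectories(field, rbind(inlet_point), dt_flow = dt_flow,
                     n_steps = n_steps)[[1L]]
}

#' Interpolate a trajectory position
#'
#' Linear interpolation of the trajectory position at time(s) `t` (ms since
#' the thread entered the inlet). Exact at sample times.
#'
#' @param traj a [integrate_trajectory()] object.
#' @param t time(s) in ms within `[0, traj$duration]`.
#' @return `length(t) x 3` position matrix (a vector for scalar `t`).
#' @export
interpolate_position <- function(traj, t) {
  if (any(t < -1e-9 | t > traj$duration + 1e-9))
    stopf("time outside the trajectory span [0, %g] ms (particle expired or not yet injected)",
          traj$duration)
  t <- pmin(pmax(t, 0), traj$duration)
  dt <- traj$dt_flow
  i <- pmin(floor(t / dt), nrow(traj$pos) - 2L)
  i <- pmax(i, 0L)
  f <- t / dt - i
  ## last interval may be shorter than dt (outlet clamp): rescale
  tl <- traj$t
  n <- length(tl)
  last <- i == n - 2L
  if (any(last)) {
    w <- (tl[n] - tl[n - 1L])
    f[last] <- pmin((t[last] - tl[n - 1L]) / w, 1)
  }
  p <- traj$pos[i + 1L, , drop = FALSE] * (1 - f) +
       traj$pos[i + 2L, , drop = FALSE] * f
  if (length(t) == 1L) drop(p) else p
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory #%d: %d samples, dt = %.4g ms, transit %.4g ms, r/R = %.3f>\n",
              x$id, length(x$t), x$dt_flow, x$duration, x$r_frac))
  invisible(x)
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat(sprintf("<trajectory_bundle: %d trajectories>\n", length(x)))
  invisible(x)
}
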