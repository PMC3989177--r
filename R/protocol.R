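## Protocol definition and per-TR event scheduling for the 3D ToF SPGR
## sequence: MOTSA slab planning, phase-encode phases, flow-compensation
## gradient design (first-moment nulling), spatial presaturation and the
## ordered event list of one repetition.

#' Define a ToF imaging protocol
#'
#' All timing in ms, lengths in mm, angles in degrees (converted to rad
#' internally). The acquisition clock step is
#' `dt = readout_window / matrix[1]` (one k-space sample per step).
#'
#' @param TE echo time (RF centre to echo centre), ms.
#' @param TR repetition time, ms.
#' @param FA nominal flip angle, degrees (at the slab centre when TONE is
#'   on).
#' @param matrix acquisition matrix `c(Nx, Ny, Nz_per_slab)` (frequency,
#'   phase, slice encodes).
#' @param FOV field of view `c(x, y, z)`, mm.
#' @param slab_width excited slab width, mm (defaults to `FOV[3]`:
#'   single-slab volume).
#' @param slab_overlap overlap of consecutive MOTSA slabs, mm.
#' @param readout_window signal sampling window, ms.
#' @param rf_duration rectangular RF pulse duration, ms.
#' @param rf_substeps substeps for moving spins during the pulse.
#' @param TONE list `(enabled, span)`: `span` is the total edge-to-edge
#'   flip-angle ramp in degrees.
#' @param presat list `(enabled, side, width, gap)`: saturation band of
#'   `width` mm, `gap` mm beyond the slab edge on `side` (+1: above,
#'   -1: below).
#' @param flow_comp named logical vector, axes `x`, `y`, `z`: first-moment
#'   nulling of the encoding on that axis.
#' @param B0 main field, T.
#' @param recon_matrix in-plane zero-padded reconstruction matrix.
#' @param line_order `"sequential"` ky within ascending kz.
#' @return an object of class `tof_protocol`.
#' @examples
#' p <- tof_protocol(TE = 4.7, TR = 40, FA = 20, matrix = c(64, 64, 16),
#'                   FOV = c(64, 64, 44), slab_width = 44)
#' @export
tof_protocol <- function(TE, TR, FA,
                         matrix = c(224, 160, 44),
                         FOV = c(175, 134, 144),
                         slab_width = NULL,
                         slab_overlap = 0,
                         readout_window = 6,
                         rf_duration = 0.6,
                         rf_substeps = 8L,
                         TONE = list(enabled = FALSE, span = 20),
                         presat = list(enabled = FALSE, side = +1,
                                       width = 40, gap = 5),
                         flow_comp = c(x = FALSE, y = FALSE, z = FALSE),
                         B0 = 1.5,
                         recon_matrix = 256,
                         line_order = "sequential") {
  if (TE <= 0 || TR <= 0 || TE >= TR) stopf("need 0 < TE < TR")
  if (length(matrix) != 3) stopf("matrix must be c(Nx, Ny, Nz)")
  slab_width <- slab_width %||% FOV[3]
  if (slab_overlap >= slab_width) stopf("slab_overlap must be < slab_width")
  slice_thickness <- slab_width / matrix[3]
  dt <- readout_window / matrix[1]
  if (TE - readout_window / 2 < rf_duration / 2 - 1e-9)
    stopf("TE too short: readout window (%g ms) overlaps the RF pulse", readout_window)
  if (TE + readout_window / 2 > TR + 1e-9)
    stopf("readout window extends past TR")
  p <- list(TE = TE, TR = TR, FA = deg2rad(FA),
            matrix = as.integer(matrix), FOV = FOV,
            slab_width = slab_width, slab_overlap = slab_overlap,
            slice_thickness = slice_thickness,
            readout_window = readout_window, dt = dt,
            rf_duration = rf_duration, rf_substeps = as.integer(rf_substeps),
            TONE = list(enabled = isTRUE(TONE$enabled),
                        span = deg2rad(TONE$span %||% 20)),
            presat = list(enabled = isTRUE(presat$enabled),
                          side = presat$side %||% 1,
                          width = presat$width %||% 40,
                          gap = presat$gap %||% 5),
            flow_comp = c(x = isTRUE(flow_comp[["x"]]),
                          y = isTRUE(flow_comp[["y"]]),
                          z = isTRUE(flow_comp[["z"]])),
            B0 = B0, recon_matrix = recon_matrix,
            line_order = line_order)
  class(p) <- "tof_protocol"
  p
}

#' @export
print.tof_protocol <- function(x, ...) {
  cat(sprintf("<tof_protocol: TE/TR/FA = %g/%g/%.0f deg, matrix %dx%dx%d, FOV %gx%gx%g mm, slabs %g/%g mm%s%s>\n",
              x$TE, x$TR, rad2deg(x$FA), x$matrix[1], x$matrix[2], x$matrix[3],
              x$FOV[1], x$FOV[2], x$FOV[3], x$slab_width, x$slab_overlap,
              if (x$TONE$enabled) sprintf(", TONE %g deg", rad2deg(x$TONE$span)) else "",
              if (x$presat$enabled) ", presat" else ""))
  invisible(x)
}

#' Plan MOTSA slabs
#'
#' Minimal set of slabs of width `slab_width`, stepping by
#' `slab_width - overlap`, covering the axial field of view
#' `[z0, z0 + FOV_z]`.
#'
#' @param FOV_z axial extent to cover, mm.
#' @param slab_width slab width, mm.
#' @param overlap overlap of consecutive slabs, mm (`0 <= overlap <
#'   slab_width`).
#' @param z0 lower edge of the field of view (default centred on 0).
#' @return object of class `slab_plan`: data.frame with `z_min`, `z_max`.
#' @examples
#' plan_slabs(144, 44, 8)  # 4 slabs
#' @export
plan_slabs <- function(FOV_z, slab_width, overlap = 0, z0 = -FOV_z / 2) {
  if (overlap < 0 || overlap >= slab_width) stopf("need 0 <= overlap < slab_width")
  step <- slab_width - overlap
  n <- if (FOV_z <= slab_width) 1L else ceiling((FOV_z - slab_width) / step - 1e-9) + 1L
  z_min <- z0 + (seq_len(n) - 1L) * step
  plan <- data.frame(slab = seq_len(n), z_min = z_min, z_max = z_min + slab_width)
  attr(plan, "overlap") <- overlap
  attr(plan, "slab_width") <- slab_width
  class(plan) <- c("slab_plan", "data.frame")
  plan
}

#' Phase-encode phase at a position
#'
#' Instantaneous phase imparted by the ky/kz phase-encode blips:
#' `2 pi (ky y / FOV_y + kz z_rel / slab_width)` with `z_rel` measured from
#' the slab centre. `ky` runs over `[-Ny/2, Ny/2)`, `kz` over
#' `[-Nz/2, Nz/2)`.
#'
#' @param protocol a [tof_protocol()].
#' @param ky,kz integer k-space indices.
#' @param position length-3 vector or `n x 3` matrix of positions, mm.
#' @param slab `c(z_min, z_max)` of the current slab (default: centred on
#'   0).
#' @return phase(s) in rad.
#' @export
phase_encode_offsets <- function(protocol, ky, kz, position,
                                 slab = c(-protocol$slab_width / 2,
                                          protocol$slab_width / 2)) {
  Ny <- protocol$matrix[2]; Nz <- protocol$matrix[3]
  if (ky < -Ny / 2 || ky >= Ny / 2) stopf("ky index %d out of range", ky)
  if (kz < -Nz / 2 || kz >= Nz / 2) stopf("kz index %d out of range", kz)
  pos <- rbind(position)
  z_rel <- pos[, 3] - mean(slab)
  phi <- 2 * pi * (ky * pos[, 2] / protocol$FOV[2] +
                   kz * z_rel / protocol$slab_width)
  phi <- unname(phi)
  if (is.null(dim(position))) drop(phi) else phi
}

#' Piecewise-constant gradient event
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param amplitude lobe amplitudes, mT/m.
#' @param duration lobe durations, ms.
#' @param start start time of the first lobe within the TR, ms; lobes play
#'   back to back.
#' @return object of class `gradient_event`.
#' @export
gradient_event <- function(axis, amplitude, duration, start) {
  if (any(duration <= 0)) stopf("lobe durations must be > 0")
  ends <- start + cumsum(duration)
  structure(list(axis = axis, amplitude = amplitude, duration = duration,
                 start = c(start, utils::head(ends, -1)), end = ends),
            class = "gradient_event")
}

#' Gradient moments
#'
#' Zeroth and first moments of one or more piecewise-constant gradient
#' events, evaluated at `t_end` with the first moment taken about `about`:
#' `m0 = int G dt`, `m1 = int G (t - about) dt`. Amplitudes in mT/m give
#' moments in mT*ms/m and mT*ms^2/m.
#'
#' @param events a `gradient_event` or list of them (same axis).
#' @param t_end evaluation time, ms (lobes are truncated there).
#' @param about reference time for the first moment (default `t_end`).
#' @return named vector `c(m0, m1)`.
#' @export
gradient_moments <- function(events, t_end, about = t_end) {
  if (inherits(events, "gradient_event")) events <- list(events)
  m0 <- 0; m1 <- 0
  for (ev in events) {
    for (i in seq_along(ev$amplitude)) {
      a <- ev$start[i]; b <- min(ev$end[i], t_end)
      if (b <= a) next
      A <- ev$amplitude[i]
      m0 <- m0 + A * (b - a)
      m1 <- m1 + A * ((b^2 - a^2) / 2 - about * (b - a))
    }
  }
  c(m0 = m0, m1 = m1)
}

#' Design a flow-compensated readout prephaser
#'
#' Replaces a single-lobe prephaser by a back-to-back bipolar pair (each
#' half the original duration) whose zeroth moment at the echo centre
#' equals the base prephaser's while the first moment of prephaser plus
#' readout gradient vanishes there -- velocity-induced phase of
#' constant-velocity spins is nulled at the echo.
#'
#' @param prephaser the base single-lobe [gradient_event()].
#' @param echo_time echo-centre time within the TR, ms.
#' @param readout optional readout [gradient_event()] included in the
#'   first-moment balance (truncated at the echo).
#' @return a two-lobe `gradient_event` occupying the same time window.
#' @export
flow_comp_waveform <- function(prephaser, echo_time, readout = NULL) {
  if (length(prephaser$amplitude) != 1L)
    stopf("base prephaser must be a single lobe")
  d <- prephaser$duration / 2
  t0 <- prephaser$start[1]
  if (t0 + 2 * d > echo_time + 1e-9)
    stopf("infeasible timing: compensation lobes extend past the echo")
  target <- gradient_moments(prephaser, echo_time)
  m_ro <- if (is.null(readout)) c(m0 = 0, m1 = 0) else
    gradient_moments(readout, echo_time)
  ## lobe centres relative to echo
  c1 <- t0 + d / 2 - echo_time
  c2 <- t0 + 3 * d / 2 - echo_time
  ## A1 d + A2 d = m0_base ; A1 d c1 + A2 d c2 = -m1_readout
  A <- solve(rbind(c(d, d), c(d * c1, d * c2)),
             c(target[["m0"]], -m_ro[["m1"]]))
  gradient_event(prephaser$axis, A, c(d, d), t0)
}

#' Readout gradient and base prephaser in physical units
#'
#' The readout gradient amplitude realises one k-space step per sampling
#' interval (`gamma G dt FOV_x = 2 pi`); the base prephaser is a single
#' lobe just before the readout whose zeroth moment centres the echo.
#'
#' @param protocol a [tof_protocol()].
#' @param prephaser_duration lobe duration, ms.
#' @return list with `readout` and `prephaser` [gradient_event()]s and the
#'   echo time `t_echo` (ms from TR start).
#' @export
readout_gradients <- function(protocol, prephaser_duration = 1) {
  Nx <- protocol$matrix[1]
  dt <- protocol$dt
  t_echo <- protocol$rf_duration / 2 + protocol$TE
  t_ro0 <- t_echo - protocol$readout_window / 2
  ## G in mT/m = 1e-6 T/mm; gamma G dt FOVx = 2*pi per k step
  G <- 2 * pi / (GAMMA_H * 1e-6 * dt * protocol$FOV[1])  # mT/m
  readout <- gradient_event("x", G, protocol$readout_window, t_ro0)
  ## zeroth moment of readout from start to echo = G * rw/2; prephase with
  ## the opposite area so the echo sits at the window centre
  d <- min(prephaser_duration, max(t_ro0 - protocol$rf_duration, 0.1))
  pre <- gradient_event("x", -G * (protocol$readout_window / 2) / d, d, t_ro0 - d)
  list(readout = readout, prephaser = pre, t_echo = t_echo)
}

#' Gradient phase accrued by a moving spin
#'
#' Numerically integrates `gamma * G(t) * x(t)` for a spin moving at
#' constant velocity along the gradient axis, up to `t_end`. Used to
#' verify moment nulling of the flow-compensated readout.
#'
#' @param events list of [gradient_event()]s on one axis.
#' @param x0 position at t = 0, mm.
#' @param v velocity along the axis, mm/ms.
#' @param t_end end of integration (echo centre), ms.
#' @param n_steps quadrature resolution.
#' @return phase in rad.
#' @export
gradient_phase <- function(events, x0 = 0, v = 0, t_end, n_steps = 20000L) {
  if (inherits(events, "gradient_event")) events <- list(events)
  tt <- seq(0, t_end, length.out = n_steps + 1L)
  G <- numeric(length(tt))
  for (ev in events) {
    for (i in seq_along(ev$amplitude)) {
      G <- G + ev$amplitude[i] * (tt >= ev$start[i] & tt < min(ev$end[i], t_end))
    }
  }
  x <- x0 + v * tt
  ## trapezoid; G piecewise constant so midpoint via shifted samples
  f <- GAMMA_H * 1e-6 * G * x
  sum((f[-1] + f[-length(f)]) / 2) * (tt[2] - tt[1])
}

#' Apply a spatial presaturation pulse
#'
#' Every particle inside the band at time `t` receives an ideal 90-degree
#' pulse followed by a spoiler: its magnetization is zeroed. Spins that
#' leave the band recover by T1 before reaching the imaging slab, which is
#' what separates co- and counter-flowing vessels.
#'
#' @param particles a `particle_set`.
#' @param band `c(z_min, z_max)` of the saturation band, mm.
#' @param t simulation time, ms.
#' @return the updated `particle_set`.
#' @export
presaturate <- function(particles, band, t = 0) {
  pos <- particle_positions(particles, t)
  z <- pos[, 3]
  hit <- !is.na(z) & z >= band[1] & z <= band[2]
  particles$M[hit, ] <- 0
  particles
}

## saturation band of a slab given the protocol (side relative to slab)
presat_band <- function(protocol, slab) {
  side <- protocol$presat$side
  if (side > 0) c(slab[2] + protocol$presat$gap,
                  slab[2] + protocol$presat$gap + protocol$presat$width)
  else c(slab[1] - protocol$presat$gap - protocol$presat$width,
         slab[1] - protocol$presat$gap)
}

#' Event schedule of one TR
#'
#' Deterministic ordered event list of a single repetition for line
#' `(ky, kz)`: optional presaturation, RF excitation, phase encode +
#' readout prephase, the `Nx` readout samples centred on the echo, and the
#' final spoiler.
#'
#' @param protocol a [tof_protocol()].
#' @param slab `c(z_min, z_max)`, mm.
#' @param ky,kz k-space line indices.
#' @return data.frame with columns `event` and `time` (ms from TR start),
#'   plus attributes `t_echo` and `sample_times`.
#' @export
tr_schedule <- function(protocol, slab, ky, kz) {
  Nx <- protocol$matrix[1]
  ## index validity check (errors on out-of-range)
  phase_encode_offsets(protocol, ky, kz, c(0, 0, mean(slab)), slab)
  tau <- protocol$rf_duration
  t_echo <- tau / 2 + protocol$TE
  ts <- t_echo + ((0:(Nx - 1)) - Nx / 2) * protocol$dt
  ev <- data.frame(event = character(0), time = numeric(0))
  if (protocol$presat$enabled)
    ev <- rbind(ev, data.frame(event = "presat", time = 0))
  ev <- rbind(ev,
              data.frame(event = "rf", time = 0),
              data.frame(event = "encode", time = tau),
              data.frame(event = "sample", time = ts),
              data.frame(event = "spoil", time = protocol$TR))
  if (ts[1] < tau - 1e-9) stopf("TE too short for scheduled events")
  attr(ev, "t_echo") <- t_echo
  attr(ev, "sample_times") <- ts
  attr(ev, "ky") <- ky
  attr(ev, "kz") <- kz
  ev
}

#' K-space line ordering of a slab acquisition
#'
#' One row per TR: sequential ky within each kz, kz ascending (the default
#' ordering; it only affects transient-state artifacts).
#' @param protocol a [tof_protocol()].
#' @return data.frame with integer columns `ky`, `kz` (`Ny * Nz` rows).
#' @export
line_order <- function(protocol) {
  Ny <- protocol$matrix[2]; Nz <- protocol$matrix[3]
  kys <- (0:(Ny - 1)) - Ny %/% 2
  kzs <- (0:(Nz - 1)) - Nz %/% 2
  data.frame(ky = rep(kys, times = Nz), kz = rep(kzs, each = Ny))
}
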