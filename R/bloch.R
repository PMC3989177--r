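## Discrete-time analytic Bloch evolution. Between events the magnetization
## of every spin packet evolves by closed-form operators:
##
##   relaxation    Mxy *= exp(-dt/T2),  Mz -> M0 + (Mz - M0) exp(-dt/T1)
##   precession    (Mx, My) rotated about z by (total offset) * dt
##   excitation    rotation by alpha_eff about the effective-field axis,
##                 tilted from +z by theta = atan2(omega1, domega) with
##                 omega1 = alpha/tau; alpha_eff = tau sqrt(omega1^2+domega^2)
##
## Convention: RF phase 0 puts the effective-field azimuth along +x and a
## positive on-resonance flip rotates +z towards -y (right-handed rotation
## about +x). Any self-consistent convention yields identical magnitude
## images.
##
## All operators accept an n x 3 matrix of magnetization vectors and are
## vectorised over spins.

as_M <- function(M) {
  if (is.null(dim(M))) matrix(M, 1, 3) else M
}

#' Relaxation operator
#'
#' Applies T2 decay to the transverse components and T1 recovery of the
#' longitudinal component towards the tissue equilibrium `M0 = rho`.
#'
#' @param M magnetization: length-3 vector or `n x 3` matrix.
#' @param dt time interval, ms (`>= 0`).
#' @param tissue a [tissue_properties()] object, or a list with vectors
#'   `T1`, `T2`, `rho` recycled over the rows of `M`.
#' @return magnetization of the same shape as `M`.
#' @export
relax <- function(M, dt, tissue) {
  if (dt < 0) stopf("dt must be >= 0")
  one <- is.null(dim(M)); M <- as_M(M)
  if (any(tissue$T1 <= 0) || any(tissue$T2 <= 0)) stopf("non-positive T1/T2")
  E1 <- exp(-dt / tissue$T1); E2 <- exp(-dt / tissue$T2)
  out <- cbind(M[, 1] * E2, M[, 2] * E2,
               tissue$rho + (M[, 3] - tissue$rho) * E1)
  if (one) drop(out) else out
}

#' Precession operator
#'
#' Rotates the transverse magnetization about +z by `total_offset * dt`
#' (phase-encode gradients, field inhomogeneity, chemical shift).
#'
#' @inheritParams relax
#' @param total_offset angular frequency offset(s), rad/ms (recycled).
#' @export
precess <- function(M, dt, total_offset) {
  if (dt < 0) stopf("dt must be >= 0")
  one <- is.null(dim(M)); M <- as_M(M)
  out <- rotz(M, total_offset * dt)
  if (one) drop(out) else out
}

## rotation of the transverse plane about +z by angle(s) phi (right-handed)
rotz <- function(M, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  cbind(M[, 1] * c_ - M[, 2] * s_,
        M[, 1] * s_ + M[, 2] * c_,
        M[, 3])
}

## Rodrigues rotation of rows of M about unit axis u (1x3 or n x 3) by
## angle phi (scalar or length n). Preserves |M| to machine precision.
rot_axis <- function(M, u, phi) {
  if (is.null(dim(u))) u <- matrix(u, nrow(M), 3, byrow = TRUE)
  c_ <- cos(phi); s_ <- sin(phi)
  dotp <- rowSums(u * M)
  crossx <- u[, 2] * M[, 3] - u[, 3] * M[, 2]
  crossy <- u[, 3] * M[, 1] - u[, 1] * M[, 3]
  crossz <- u[, 1] * M[, 2] - u[, 2] * M[, 1]
  cbind(M[, 1] * c_ + crossx * s_ + u[, 1] * dotp * (1 - c_),
        M[, 2] * c_ + crossy * s_ + u[, 2] * dotp * (1 - c_),
        M[, 3] * c_ + crossz * s_ + u[, 3] * dotp * (1 - c_))
}

#' Effective flip angle and tilt under off-resonance
#'
#' For a rectangular pulse of nominal flip `alpha` and duration `tau`, the
#' on-resonance rotation rate is `omega1 = alpha / tau`. An off-resonance
#' offset `domega` tilts the effective field away from the transverse
#' plane and increases the total rotation:
#' `alpha_eff = tau * sqrt(omega1^2 + domega^2)`,
#' `theta = atan2(omega1, domega)` (angle of the effective field from +z).
#'
#' @param alpha nominal flip angle, rad.
#' @param tau pulse duration, ms (> 0).
#' @param domega off-resonance angular frequency, rad/ms.
#' @return list with `alpha_eff` (rad) and `theta` (rad); vectorised.
#' @export
effective_flip <- function(alpha, tau, domega = 0) {
  if (any(tau <= 0)) stopf("tau must be > 0")
  omega1 <- alpha / tau
  list(alpha_eff = tau * sqrt(omega1^2 + domega^2),
       theta = atan2(omega1, domega))
}

#' RF pulse description
#'
#' @param alpha nominal flip angle, rad.
#' @param phase RF phase, rad (azimuth of the effective-field axis).
#' @param tau pulse duration, ms.
#' @param n_substeps number of sub-rotations the pulse is divided into;
#'   moving spins have their position refreshed at every substep and may
#'   enter or leave the excited slab mid-pulse.
#' @return an object of class `rf_pulse`.
#' @export
rf_pulse <- function(alpha, phase = 0, tau = 1, n_substeps = 8L) {
  if (tau <= 0) stopf("tau must be > 0")
  if (n_substeps < 1) stopf("n_substeps must be >= 1")
  structure(list(alpha = alpha, phase = phase, tau = tau,
                 n_substeps = as.integer(n_substeps)),
            class = "rf_pulse")
}

#' Apply an RF excitation pulse
#'
#' Divides the pulse into `n_substeps` sub-rotations. At each substep the
#' particle positions are refreshed through `position_provider(t)` (ms from
#' pulse start); spins outside the slab's (ideal rectangular) excitation
#' profile receive no rotation for that substep, so spins that exit the
#' slab mid-pulse are only partially flipped. With TONE enabled the nominal
#' flip is ramped linearly along z via [tone_flip()].
#'
#' @param M `n x 3` magnetization matrix (or length-3 vector).
#' @param pulse an [rf_pulse()].
#' @param domega off-resonance offset(s) rad/ms (recycled over spins).
#' @param position_provider `function(t_ms) -> n x 3` positions; may return
#'   `NA` rows for spins with no position (never excited). `NULL` treats
#'   all spins as stationary and inside the slab.
#' @param slab optional `c(z_min, z_max)` of the excited slab (mm).
#' @param tone optional list `(span, flow_sign)` for the TONE ramp (rad).
#' @return magnetization of the same shape as `M`.
#' @export
rf_excite <- function(M, pulse, domega = 0, position_provider = NULL,
                      slab = NULL, tone = NULL) {
  one <- is.null(dim(M)); M <- as_M(M)
  n <- nrow(M)
  nss <- pulse$n_substeps
  dtau <- pulse$tau / nss
  domega <- rep_len(domega, n)
  for (k in seq_len(nss)) {
    tk <- (k - 0.5) * dtau
    if (is.null(position_provider)) {
      inside <- rep(TRUE, n)
      z <- NULL
    } else {
      pos <- position_provider(tk)
      z <- pos[, 3]
      inside <- !is.na(z)
      if (!is.null(slab)) inside <- inside & z >= slab[1] & z <= slab[2]
    }
    if (!any(inside)) next
    alpha <- rep_len(pulse$alpha, n)
    if (!is.null(tone) && !is.null(slab) && !is.null(z)) {
      alpha[inside] <- tone_flip(pulse$alpha, z[inside], slab,
                                 span = tone$span,
                                 flow_direction = tone$flow_sign %||% 1)
    }
    ef <- effective_flip(alpha[inside], pulse$tau, domega[inside])
    st <- sin(ef$theta)
    u <- cbind(st * cos(pulse$phase), st * sin(pulse$phase), cos(ef$theta))
    ## positive flip rotates +z towards -y for phase 0: rotate about +x by
    ## +alpha in the right-handed sense
    M[inside, ] <- rot_axis(M[inside, , drop = FALSE], u, ef$alpha_eff / nss)
  }
  if (one) drop(M) else M
}

#' TONE ramped flip angle
#'
#' Linear flip-angle ramp along the slab: the nominal angle holds at the
#' slab centre and the ramp spans `span` radians edge-to-edge, increasing
#' in the flow direction so that spins entering the slab see the smallest
#' flip (`nominal - span/2`) and exit at the largest.
#'
#' @param alpha nominal flip angle at the slab centre, rad.
#' @param z particle z position(s), mm; must lie inside the slab.
#' @param slab `c(z_min, z_max)` mm.
#' @param span total edge-to-edge ramp, rad (0 disables the ramp).
#' @param flow_direction +1 for flow towards +z, -1 for the opposite.
#' @return flip angle(s) at `z`, rad.
#' @export
tone_flip <- function(alpha, z, slab, span = 0, flow_direction = 1) {
  if (any(z < slab[1] - 1e-9 | z > slab[2] + 1e-9))
    stopf("z outside the slab [%g, %g]", slab[1], slab[2])
  zc <- mean(slab)
  alpha + span * ((z - zc) / (slab[2] - slab[1])) * flow_direction
}

#' Ideal spoiler
#'
#' Destroys the transverse magnetization, keeping `Mz`.
#' @param M length-3 vector or `n x 3` matrix.
#' @export
spoil <- function(M) {
  one <- is.null(dim(M)); M <- as_M(M)
  M[, 1] <- 0; M[, 2] <- 0
  if (one) drop(M) else M
}

#' Closed-form spoiled gradient-echo steady state
#'
#' Ernst formula for the post-pulse transverse magnetization of stationary,
#' ideally spoiled spins: `M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with
#' `E1 = exp(-TR/T1)`. Used as the analytic reference for the simulated
#' steady state.
#'
#' @param alpha flip angle, rad.
#' @param TR repetition time, ms.
#' @param T1 longitudinal relaxation time, ms.
#' @param M0 equilibrium magnetization (proton density).
#' @export
ernst_signal <- function(alpha, TR, T1, M0 = 1) {
  E1 <- exp(-TR / T1)
  M0 * sin(alpha) * (1 - E1) / (1 - E1 * cos(alpha))
}
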