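## The k-space synthesis loop. Signal model: after the phase encodes, each
## readout sample m (kx = m - Nx/2) measures
##
##   S(kx, ky, kz) = sum_p V_p (Mx_p + i My_p)
##
## with the encoding phase exp(-i 2 pi k . r) imparted by precession
## operators: an instantaneous phase-encode rotation at its scheduled time
## and an incremental readout rotation of -2 pi x(t)/FOV_x per sample step,
## prephased by +2 pi (Nx/2) x/FOV_x. Between samples the MRA clock
## advances by dt = readout_window / Nx: moving-particle positions are
## re-interpolated on the flow grid, relaxation is applied, and particles
## are retired at the outlet / injected at the inlet.
##
## Implementation: for each flowing component the full set of particles
## that will ever exist during the scan (initial population + injection
## schedule) is laid out up front, sorted by birth time; every TR operates
## on the window of particles alive at some point inside it, with per-
## sample alive masks. Unborn particles sit at equilibrium (no transverse
## magnetization, so they cannot contribute before their first pulse) and
## expired particles are masked out of every position-dependent operator
## and out of the signal sum.

#' Complex signal from a particle collection
#'
#' Volume-weighted sum of transverse magnetization over all (alive)
#' particles: `S = sum V_i (Mx_i + i My_i)`. Proton density enters through
#' the equilibrium scale of `M`.
#'
#' @param particles a `particle_set`.
#' @param t optional time (ms): restricts the sum to particles alive then.
#' @return a complex scalar.
#' @export
sample_signal <- function(particles, t = NULL) {
  keep <- if (is.null(t)) rep(TRUE, length(particles$label))
          else particles_alive(particles, t)
  sum(particles$volume[keep] *
        complex(real = particles$M[keep, 1], imaginary = particles$M[keep, 2]))
}

## ---- engine state ---------------------------------------------------------

#' Create an acquisition state
#'
#' Prepares one particle component (flowing or stationary) for the k-space
#' loop over a slab: lays out the injection schedule for the whole scan and
#' precomputes relaxation factors on the sampling clock.
#'
#' @param particles a `particle_set` (one tissue component).
#' @param protocol a [tof_protocol()].
#' @param slab `c(z_min, z_max)` of the excited slab, mm.
#' @param n_tr total number of repetitions that will be run (including
#'   dummy cycles); fixes the injection horizon.
#' @return an environment of class `acq_state`.
#' @export
acq_state <- function(particles, protocol, slab, n_tr = NULL) {
  stopifnot(inherits(particles, "particle_set"))
  st <- new.env(parent = emptyenv())
  st$protocol <- protocol
  st$slab <- slab
  st$zc <- mean(slab)
  st$time <- 0
  st$stationary <- particles$stationary
  ti <- particles$tissues[[1L]]
  st$tissue <- ti
  dt <- protocol$dt
  st$E1s <- exp(-dt / ti$T1); st$E2s <- exp(-dt / ti$T2)
  st$rho <- ti$rho
  st$domega <- ti$domega
  st$flow_sign <- attr(particles, "flow_sign") %||% 1
  n_tr <- n_tr %||% (protocol$matrix[2] * protocol$matrix[3])
  st$t_total <- n_tr * protocol$TR
  if (particles$stationary) {
    ## spins outside the excited slab are never tipped and cannot emit
    ## signal: drop them for the whole slab simulation
    keep <- particles$pos0[, 3] >= slab[1] & particles$pos0[, 3] <= slab[2]
    st$x <- particles$pos0[keep, 1]; st$y <- particles$pos0[keep, 2]
    st$z <- particles$pos0[keep, 3]
    st$vol <- particles$volume[keep]
    st$Mx <- particles$M[keep, 1]; st$My <- particles$M[keep, 2]
    st$Mz <- particles$M[keep, 3]
    ## per-sample readout increment: rotation by ux = -2 pi x / FOV_x
    st$ux <- -2 * pi * st$x / protocol$FOV[1]
    st$cu <- cos(st$ux); st$su <- sin(st$ux)
    return(structure(st, class = "acq_state"))
  }
  if (abs(particles$t0) > 1e-12) stopf("engine expects particle_set with t0 = 0")
  bundle <- particles$bundle
  tf <- attr(particles, "transform") %||%
    list(origin = c(0, 0, 0), zsign = 1)
  m <- length(bundle)
  off <- integer(m); nn <- integer(m); dtf <- numeric(m); dur <- numeric(m)
  ntot <- sum(vapply(bundle, function(tr) nrow(tr$pos), integer(1)))
  PX <- numeric(ntot); PY <- numeric(ntot); PZ <- numeric(ntot)
  at <- 0L
  for (i in seq_len(m)) {
    tr <- bundle[[i]]
    k <- nrow(tr$pos)
    off[i] <- at; nn[i] <- k; dtf[i] <- tr$dt_flow; dur[i] <- tr$duration
    PX[at + seq_len(k)] <- tr$pos[, 1] + tf$origin[1]
    PY[at + seq_len(k)] <- tr$pos[, 2] + tf$origin[2]
    PZ[at + seq_len(k)] <- tr$pos[, 3] * tf$zsign + tf$origin[3]
    at <- at + k
  }
  st$off <- off; st$nn <- nn; st$dtf <- dtf; st$dur <- dur
  st$PX <- PX; st$PY <- PY; st$PZ <- PZ
  st$max_speed <- max(vapply(bundle, function(tr) max(tr$speed), numeric(1)))
  ## universe: particles present at t = 0 plus the whole injection schedule
  sd <- particles$seedings
  inj_counts <- pmax(0L, floor(st$t_total / sd$dt_inj - 1e-9))
  u_traj <- c(particles$traj, rep(seq_len(m), inj_counts))
  u_tshift <- c(particles$tshift,
                -(sequence(inj_counts)) * sd$dt_inj[rep(seq_len(m), inj_counts)])
  u_vol <- c(particles$volume, sd$volume[rep(seq_len(m), inj_counts)])
  birth <- pmax(0, -u_tshift)
  death <- dur[u_traj] - u_tshift
  ord <- order(birth)
  st$u_traj <- u_traj[ord]; st$u_tshift <- u_tshift[ord]
  st$u_vol <- u_vol[ord]
  st$u_birth <- birth[ord]; st$u_death <- death[ord]
  st$hi <- 0L
  ## active window (starts empty; first TR pulls in the initial particles)
  st$a_idx <- integer(0)
  st$a_traj <- integer(0); st$a_tshift <- numeric(0); st$a_vol <- numeric(0)
  st$Mx <- numeric(0); st$My <- numeric(0); st$Mz <- numeric(0)
  structure(st, class = "acq_state")
}

## refresh the active window for a TR spanning [t0, t1]
engine_window <- function(st, t0, t1) {
  keep <- st$u_death[st$a_idx] >= t0 - 1e-9
  a_idx <- st$a_idx[keep]
  Mx <- st$Mx[keep]; My <- st$My[keep]; Mz <- st$Mz[keep]
  hi <- st$hi
  nuniv <- length(st$u_birth)
  while (hi < nuniv && st$u_birth[hi + 1L] <= t1 + 1e-9) hi <- hi + 1L
  if (hi > st$hi) {
    new <- (st$hi + 1L):hi
    a_idx <- c(a_idx, new)
    Mx <- c(Mx, numeric(length(new)))
    My <- c(My, numeric(length(new)))
    Mz <- c(Mz, rep(st$rho, length(new)))
  }
  st$hi <- hi
  st$a_idx <- a_idx
  st$a_traj <- st$u_traj[a_idx]
  st$a_tshift <- st$u_tshift[a_idx]
  st$a_vol <- st$u_vol[a_idx]
  st$Mx <- Mx; st$My <- My; st$Mz <- Mz
  invisible(st)
}

## gather a coordinate of the active particles at absolute time t;
## returns list(idx = alive indices, x/y/z as requested)
engine_gather <- function(st, t, what = "x") {
  tt <- t + st$a_tshift
  alive <- which(tt >= -1e-9 & tt <= st$dur[st$a_traj] + 1e-9)
  if (length(alive) == 0L)
    return(list(idx = alive))
  tr <- st$a_traj[alive]
  ttl <- pmax(tt[alive], 0)
  ii <- pmin(floor(ttl / st$dtf[tr]), st$nn[tr] - 2L)
  fr <- ttl / st$dtf[tr] - ii
  g <- st$off[tr] + ii + 1L
  out <- list(idx = alive)
  if ("x" %in% what) out$x <- st$PX[g] * (1 - fr) + st$PX[g + 1L] * fr
  if ("y" %in% what) out$y <- st$PY[g] * (1 - fr) + st$PY[g + 1L] * fr
  if ("z" %in% what) out$z <- st$PZ[g] * (1 - fr) + st$PZ[g + 1L] * fr
  out
}

## rotate transverse magnetization of rows sel by phase phi
engine_rotz <- function(st, sel, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  mx <- st$Mx[sel]; my <- st$My[sel]
  st$Mx[sel] <- mx * c_ - my * s_
  st$My[sel] <- mx * s_ + my * c_
  invisible(st)
}

## relax everything over dt (scalars per component)
engine_relax <- function(st, E1, E2) {
  st$Mx <- st$Mx * E2
  st$My <- st$My * E2
  st$Mz <- st$rho + (st$Mz - st$rho) * E1
  invisible(st)
}

## RF excitation of a stationary component (positions never change, so the
## whole pulse is a single rotation per spin)
engine_rf <- function(st, tbase) {
  p <- st$protocol
  sel <- which(st$z >= st$slab[1] & st$z <= st$slab[2])
  if (length(sel) == 0L) return(invisible(st))
  z <- st$z[sel]
  alpha <- if (p$TONE$enabled)
    tone_flip(p$FA, z, st$slab, span = p$TONE$span,
              flow_direction = st$flow_sign)
  else rep(p$FA, length(sel))
  if (st$domega == 0) {
    c_ <- cos(alpha); s_ <- sin(alpha)
    my <- st$My[sel]; mz <- st$Mz[sel]
    st$My[sel] <- my * c_ - mz * s_
    st$Mz[sel] <- my * s_ + mz * c_
  } else {
    ef <- effective_flip(alpha, p$rf_duration, st$domega)
    stheta <- sin(ef$theta)
    u <- cbind(stheta, 0, cos(ef$theta))
    M <- rot_axis(cbind(st$Mx[sel], st$My[sel], st$Mz[sel]), u, ef$alpha_eff)
    st$Mx[sel] <- M[, 1]; st$My[sel] <- M[, 2]; st$Mz[sel] <- M[, 3]
  }
  invisible(st)
}

#' Run one repetition and acquire one k-space line
#'
#' Executes the full event schedule of one TR on an [acq_state()] --
#' presaturation, RF, phase encode, readout sampling, relaxation gaps and
#' the final spoiler -- and returns the `Nx` complex samples of line
#' `(ky, kz)`. The state is advanced in place (particles keep flowing
#' across TRs).
#'
#' @param st an [acq_state()].
#' @param ky,kz k-space line indices in `[-N/2, N/2)`.
#' @param sample if `FALSE`, run the TR as a dummy cycle (no readout
#'   samples returned, but identical spin history).
#' @return complex vector of length `Nx` (or `NULL` for a dummy cycle).
#' @export
acquire_line <- function(st, ky, kz, sample = TRUE) {
  p <- st$protocol
  Nx <- p$matrix[1]
  dt <- p$dt
  tau <- p$rf_duration
  t_echo <- tau / 2 + p$TE
  ts <- t_echo + ((0:(Nx - 1)) - Nx / 2) * dt
  T0 <- st$time
  if (st$stationary) {
    out <- acquire_line_stationary(st, ky, kz, sample, ts)
    st$time <- T0 + p$TR
    return(out)
  }
  engine_window(st, T0, T0 + p$TR)
  T1t <- st$tissue$T1; T2t <- st$tissue$T2
  ## --- presaturation (all active spins, at TR start) ---
  if (p$presat$enabled) {
    band <- presat_band(p, st$slab)
    gg <- engine_gather(st, T0, "z")
    sel <- gg$idx[gg$z >= band[1] & gg$z <= band[2]]
    if (length(sel)) { st$Mx[sel] <- 0; st$My[sel] <- 0; st$Mz[sel] <- 0 }
  }
  ## --- hot/cold split: after the previous spoiler only spins excited in
  ## this TR can carry transverse magnetization. Hot = spins within one
  ## TR's reach of the slab at TR start, plus spins born before the end of
  ## the pulse. Cold spins only relax longitudinally (one update per TR).
  ga <- engine_gather(st, T0, "z")
  marg <- st$max_speed * p$TR
  hot <- ga$idx[ga$z >= st$slab[1] - marg & ga$z <= st$slab[2] + marg]
  births <- st$u_birth[st$a_idx]
  newborn <- which(births > T0 + 1e-9 & births <= T0 + tau + 1e-9)
  if (length(newborn)) hot <- sort(unique(c(hot, newborn)))
  n_hot <- length(hot)
  out <- if (sample) complex(Nx) else NULL
  if (n_hot) {
    h_traj <- st$a_traj[hot]; h_tshift <- st$a_tshift[hot]
    h_vol <- st$a_vol[hot]
    h_dur <- st$dur[h_traj]; h_dtf <- st$dtf[h_traj]
    h_off <- st$off[h_traj]; h_nn <- st$nn[h_traj]
    Mx <- st$Mx[hot]; My <- st$My[hot]; Mz <- st$Mz[hot]
    gather_h <- function(t, want_xyz) {
      tt <- t + h_tshift
      alive <- which(tt >= -1e-9 & tt <= h_dur + 1e-9)
      if (!length(alive)) return(list(idx = alive))
      ttl <- pmax(tt[alive], 0)
      ii <- pmin(floor(ttl / h_dtf[alive]), h_nn[alive] - 2L)
      fr <- ttl / h_dtf[alive] - ii
      g <- h_off[alive] + ii + 1L
      res <- list(idx = alive)
      if ("x" %in% want_xyz) res$x <- st$PX[g] * (1 - fr) + st$PX[g + 1L] * fr
      if ("y" %in% want_xyz) res$y <- st$PY[g] * (1 - fr) + st$PY[g + 1L] * fr
      if ("z" %in% want_xyz) res$z <- st$PZ[g] * (1 - fr) + st$PZ[g + 1L] * fr
      res
    }
    ## --- RF excitation over [0, tau], position refreshed per substep ---
    nss <- p$rf_substeps
    dtau <- tau / nss
    for (k in seq_len(nss)) {
      gg <- gather_h(T0 + (k - 0.5) * dtau, "z")
      ok <- gg$z >= st$slab[1] & gg$z <= st$slab[2]
      sel <- gg$idx[ok]
      if (!length(sel)) next
      alpha <- if (p$TONE$enabled)
        tone_flip(p$FA, gg$z[ok], st$slab, span = p$TONE$span,
                  flow_direction = st$flow_sign)
      else rep(p$FA, length(sel))
      if (st$domega == 0) {
        phi <- alpha / nss
        c_ <- cos(phi); s_ <- sin(phi)
        my <- My[sel]; mz <- Mz[sel]
        My[sel] <- my * c_ - mz * s_
        Mz[sel] <- my * s_ + mz * c_
      } else {
        ef <- effective_flip(alpha, tau, st$domega)
        stheta <- sin(ef$theta)
        u <- cbind(stheta, 0, cos(ef$theta))
        Mr <- rot_axis(cbind(Mx[sel], My[sel], Mz[sel]), u, ef$alpha_eff / nss)
        Mx[sel] <- Mr[, 1]; My[sel] <- Mr[, 2]; Mz[sel] <- Mr[, 3]
      }
    }
    ## --- phase encode + readout prephase at t = tau (instantaneous);
    ## flow-compensated axes read the position at the echo centre, which
    ## nulls the gradient first moment for constant-velocity spins ---
    fc <- p$flow_comp
    gg <- gather_h(T0 + tau, c("x", "y", "z"))
    sel <- gg$idx
    if (length(sel)) {
      xx <- gg$x; yy <- gg$y; zz <- gg$z
      if (any(fc)) {
        ge <- gather_h(T0 + t_echo, c("x", "y", "z"))
        mm <- match(sel, ge$idx)
        okm <- !is.na(mm)
        if (fc[["x"]]) xx[okm] <- ge$x[mm[okm]]
        if (fc[["y"]]) yy[okm] <- ge$y[mm[okm]]
        if (fc[["z"]]) zz[okm] <- ge$z[mm[okm]]
      }
      phi <- -2 * pi * (ky * yy / p$FOV[2] + kz * (zz - st$zc) / p$slab_width) +
        2 * pi * (Nx / 2) * xx / p$FOV[1]
      c_ <- cos(phi); s_ <- sin(phi)
      mx <- Mx[sel]; my <- My[sel]
      Mx[sel] <- mx * c_ - my * s_
      My[sel] <- mx * s_ + my * c_
    }
    ## --- relax from end of RF to the first sample ---
    gap1 <- ts[1] - tau
    E1g <- exp(-gap1 / T1t); E2g <- exp(-gap1 / T2t)
    Mx <- Mx * E2g; My <- My * E2g; Mz <- st$rho + (Mz - st$rho) * E1g
    if (st$domega != 0) {
      c_ <- cos(st$domega * gap1); s_ <- sin(st$domega * gap1)
      mx <- Mx; Mx <- mx * c_ - My * s_; My <- mx * s_ + My * c_
    }
    ## --- readout: advance clock, refresh positions, precess, relax,
    ## retire/inject (via the alive mask), sample ---
    E1s <- st$E1s; E2s <- st$E2s
    base <- -2 * pi / p$FOV[1]
    for (m in seq_len(Nx)) {
      tm <- T0 + ts[m]
      gg <- gather_h(tm, "x")
      alive <- gg$idx
      if (m > 1L) {
        if (length(alive)) {
          phi <- base * gg$x + st$domega * dt
          c_ <- cos(phi); s_ <- sin(phi)
          mx <- Mx[alive]; my <- My[alive]
          Mx[alive] <- mx * c_ - my * s_
          My[alive] <- mx * s_ + my * c_
        }
        Mx <- Mx * E2s; My <- My * E2s; Mz <- st$rho + (Mz - st$rho) * E1s
      }
      if (sample)
        out[m] <- complex(real = sum(h_vol[alive] * Mx[alive]),
                          imaginary = sum(h_vol[alive] * My[alive]))
    }
    ## --- relax to the end of the TR, spoil, write back ---
    gap2 <- p$TR - ts[Nx]
    Mz <- st$rho + (Mz - st$rho) * exp(-gap2 / T1t)
    st$Mx[hot] <- 0; st$My[hot] <- 0; st$Mz[hot] <- Mz
  }
  ## cold spins: longitudinal recovery over the same relaxed interval
  cold <- if (n_hot) seq_along(st$Mz)[-hot] else seq_along(st$Mz)
  if (length(cold)) {
    E1c <- exp(-(p$TR - tau) / T1t)
    st$Mz[cold] <- st$rho + (st$Mz[cold] - st$rho) * E1c
  }
  st$time <- T0 + p$TR
  out
}

## readout loop for a stationary component (positions fixed; the readout
## rotation per sample is a precomputed constant-angle rotation)
acquire_line_stationary <- function(st, ky, kz, sample, ts) {
  p <- st$protocol
  Nx <- p$matrix[1]
  tau <- p$rf_duration
  if (p$presat$enabled) {
    band <- presat_band(p, st$slab)
    sel <- which(st$z >= band[1] & st$z <= band[2])
    if (length(sel)) { st$Mx[sel] <- 0; st$My[sel] <- 0; st$Mz[sel] <- 0 }
  }
  engine_rf(st, 0)
  phi <- -2 * pi * (ky * st$y / p$FOV[2] +
                    kz * (st$z - st$zc) / p$slab_width) +
    2 * pi * (Nx / 2) * st$x / p$FOV[1]
  engine_rotz(st, seq_along(st$Mx), phi)
  gap1 <- ts[1] - tau
  engine_relax(st, exp(-gap1 / st$tissue$T1), exp(-gap1 / st$tissue$T2))
  if (st$domega != 0 && length(st$Mx))
    engine_rotz(st, seq_along(st$Mx), st$domega * gap1)
  out <- if (sample) complex(Nx) else NULL
  vol <- st$vol
  for (m in seq_len(Nx)) {
    if (m > 1L) {
      mx <- st$Mx; my <- st$My
      st$Mx <- mx * st$cu - my * st$su
      st$My <- mx * st$su + my * st$cu
      engine_relax(st, st$E1s, st$E2s)
      if (st$domega != 0)
        engine_rotz(st, seq_along(st$Mx), st$domega * p$dt)
    }
    if (sample)
      out[m] <- complex(real = sum(vol * st$Mx),
                        imaginary = sum(vol * st$My))
  }
  gap2 <- p$TR - ts[Nx]
  engine_relax(st, exp(-gap2 / st$tissue$T1), exp(-gap2 / st$tissue$T2))
  st$Mx[] <- 0; st$My[] <- 0
  out
}

#' Simulate the k-space of one slab
#'
#' Loops the full line schedule (sequential ky within ascending kz) over
#' one excited slab, maintaining the particle state continuously across
#' repetitions, and returns the slab's raw k-space. A list of particle
#' components (e.g. flowing blood plus stationary tissues) is simulated
#' component by component and the k-spaces summed (the signal is linear in
#' the particles).
#'
#' @param particles a `particle_set` or list of them.
#' @param protocol a [tof_protocol()].
#' @param slab `c(z_min, z_max)` mm; default the protocol's single slab
#'   centred on 0.
#' @param n_dummy dummy repetitions run before acquisition to approach the
#'   spoiled steady state (0: start from thermal equilibrium).
#' @return a `kspace_volume`: complex array `Nx x Ny x Nz` with sampling
#'   metadata.
#' @export
simulate_slab <- function(particles, protocol, slab = NULL, n_dummy = 0L) {
  slab <- slab %||% c(-protocol$slab_width / 2, protocol$slab_width / 2)
  if (inherits(particles, "particle_set")) particles <- list(particles)
  lines <- line_order(protocol)
  n_tr <- nrow(lines) + n_dummy
  Nx <- protocol$matrix[1]; Ny <- protocol$matrix[2]; Nz <- protocol$matrix[3]
  K <- array(0 + 0i, c(Nx, Ny, Nz))
  for (comp in particles) {
    st <- acq_state(comp, protocol, slab, n_tr = n_tr)
    for (d in seq_len(n_dummy))
      acquire_line(st, 0L, 0L, sample = FALSE)
    for (r in seq_len(nrow(lines))) {
      ky <- lines$ky[r]; kz <- lines$kz[r]
      s <- acquire_line(st, ky, kz)
      K[, ky + Ny %/% 2 + 1L, kz + Nz %/% 2 + 1L] <-
        K[, ky + Ny %/% 2 + 1L, kz + Nz %/% 2 + 1L] + s
    }
  }
  structure(list(data = K, protocol = protocol, slab = slab,
                 n_dummy = n_dummy),
            class = "kspace_volume")
}

#' @export
print.kspace_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_volume: %d x %d x %d, slab [%g, %g] mm>\n",
              d[1], d[2], d[3], x$slab[1], x$slab[2]))
  invisible(x)
}

## split a flowing particle_set into n chunks by trajectory (round robin)
split_particle_set <- function(particles, n_chunks) {
  if (particles$stationary) stopf("chunking applies to flowing sets")
  m <- length(particles$bundle)
  assign_chunk <- ((seq_len(m) - 1L) %% n_chunks) + 1L
  lapply(seq_len(n_chunks), function(cc) {
    trajs <- which(assign_chunk == cc)
    if (length(trajs) == 0L) return(NULL)
    keep <- particles$traj %in% trajs
    sub <- particles
    sub$label <- particles$label[keep]
    sub$traj <- match(particles$traj[keep], trajs)
    sub$tshift <- particles$tshift[keep]
    sub$volume <- particles$volume[keep]
    sub$tissue_id <- particles$tissue_id[keep]
    sub$M <- particles$M[keep, , drop = FALSE]
    bun <- particles$bundle[trajs]
    class(bun) <- "trajectory_bundle"
    attr(bun, "inlet_radius") <- attr(particles$bundle, "inlet_radius")
    attr(bun, "field") <- attr(particles$bundle, "field")
    sub$bundle <- bun
    sub$seedings <- particles$seedings[trajs, , drop = FALSE]
    sub$next_birth <- particles$next_birth[trajs]
    for (a in c("transform", "flow_sign"))
      attr(sub, a) <- attr(particles, a)
    sub
  })
}

#' Chunked slab simulation
#'
#' Partitions the trajectories of a flowing component into `n_chunks`
#' independent bundles, simulates each separately and sums the per-chunk
#' k-spaces in chunk order — a master/agent grid reduction re-expressed as
#' an in-process contract. Spins do not interact, so the result equals the
#' single-chunk simulation to floating-point summation order.
#'
#' @inheritParams simulate_slab
#' @param n_chunks number of trajectory chunks (`>= 1`).
#' @param seed unused (the acquisition is deterministic); kept so chunked
#'   and unchunked calls share a signature with randomised callers.
#' @return a `kspace_volume`.
#' @export
run_chunked <- function(particles, protocol, slab = NULL, n_chunks = 1L,
                        seed = NULL, n_dummy = 0L) {
  slab <- slab %||% c(-protocol$slab_width / 2, protocol$slab_width / 2)
  if (n_chunks < 1L) stopf("n_chunks must be >= 1")
  chunks <- split_particle_set(particles, n_chunks)
  K <- NULL
  for (ch in chunks) {
    if (is.null(ch)) next
    k1 <- simulate_slab(ch, protocol, slab, n_dummy = n_dummy)
    K <- if (is.null(K)) k1 else { K$data <- K$data + k1$data; K }
  }
  if (is.null(K))
    K <- structure(list(data = array(0 + 0i, protocol$matrix),
                        protocol = protocol, slab = slab, n_dummy = n_dummy),
                   class = "kspace_volume")
  K
}

#' Freeze a flowing particle set
#'
#' Converts the particles alive at time `t` into a stationary set at their
#' instantaneous positions (used to check that the moving-spin machinery
#' reduces to the stationary one as the flow rate vanishes).
#'
#' @param particles a flowing `particle_set`.
#' @param t snapshot time, ms.
#' @return a stationary `particle_set`.
#' @export
freeze_particles <- function(particles, t = 0) {
  alive <- particles_alive(particles, t)
  pos <- particle_positions(particles, t)[alive, , drop = FALSE]
  ps <- list(
    label = particles$label[alive],
    traj = rep(0L, sum(alive)),
    tshift = rep(NA_real_, sum(alive)),
    volume = particles$volume[alive],
    tissue_id = particles$tissue_id[alive],
    M = particles$M[alive, , drop = FALSE],
    pos0 = pos,
    tissues = particles$tissues,
    bundle = NULL, seedings = NULL, t0 = 0,
    next_birth = numeric(0),
    n_label = sum(alive),
    stationary = TRUE
  )
  class(ps) <- "particle_set"
  ps
}
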