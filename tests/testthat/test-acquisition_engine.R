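# K-space synthesis: signal summation, line acquisition against a
# per-particle brute-force oracle, linearity, chunking, conservation.

## Naive per-particle evolution of one k-space line, written directly on
## the public Bloch operators (independent of the vectorised engine).
brute_line <- function(ps, protocol, slab, ky, kz) {
  p <- protocol
  Nx <- p$matrix[1]; dt <- p$dt; tau <- p$rf_duration
  t_echo <- tau / 2 + p$TE
  ts <- t_echo + ((0:(Nx - 1)) - Nx / 2) * dt
  ti <- ps$tissues[[1]]
  S <- complex(Nx)
  for (i in seq_along(ps$label)) {
    M <- ps$M[i, ]
    pos_at <- function(t) {
      if (ps$stationary) ps$pos0[i, ]
      else {
        tt <- t + ps$tshift[i]
        tr <- ps$bundle[[ps$traj[i]]]
        if (tt < 0 || tt > tr$duration) return(rep(NA_real_, 3))
        pp <- interpolate_position(tr, tt)
        tf <- attr(ps, "transform")
        if (!is.null(tf))
          pp <- c(pp[1] + tf$origin[1], pp[2] + tf$origin[2],
                  pp[3] * tf$zsign + tf$origin[3])
        pp
      }
    }
    ## RF with per-substep position refresh and slab profile
    nss <- if (ps$stationary) 1L else p$rf_substeps
    M <- rf_excite(M, rf_pulse(p$FA, tau = tau, n_substeps = nss),
                   domega = ti$domega,
                   position_provider = function(t) rbind(pos_at(t)),
                   slab = slab,
                   tone = if (p$TONE$enabled)
                     list(span = p$TONE$span,
                          flow_sign = attr(ps, "flow_sign") %||% 1))
    ## instantaneous encodes at t = tau
    pp <- pos_at(tau)
    if (!any(is.na(pp))) {
      phi <- -phase_encode_offsets(p, ky, kz, pp, slab) +
        2 * pi * (Nx / 2) * pp[1] / p$FOV[1]
      M <- precess(M, 1, phi)
    }
    M <- relax(M, ts[1] - tau, ti)
    M <- precess(M, 1, ti$domega * (ts[1] - tau))
    for (m in seq_len(Nx)) {
      if (m > 1) {
        pp <- pos_at(ts[m])
        if (!any(is.na(pp)))
          M <- precess(M, 1, -2 * pi * pp[1] / p$FOV[1] + ti$domega * dt)
        M <- relax(M, dt, ti)
      }
      alive <- ps$stationary ||
        (ts[m] + ps$tshift[i] >= 0 &&
         ts[m] + ps$tshift[i] <= ps$bundle[[ps$traj[i]]]$duration)
      if (alive)
        S[m] <- S[m] + ps$volume[i] * complex(real = M[1], imaginary = M[2])
    }
  }
  S
}

test_that("sample_signal sums volume-weighted transverse magnetization", {
  ps <- stationary_set(rbind(c(0, 0, 0)))
  ps$M <- rbind(c(1, 0, 0.3))
  expect_equal(sample_signal(ps), 1 + 0i)
  ## two equal particles with opposite phase cancel
  ps2 <- stationary_set(rbind(c(0, 0, 0), c(1, 1, 1)))
  ps2$M <- rbind(c(0.6, 0.2, 0), c(-0.6, -0.2, 0))
  expect_equal(sample_signal(ps2), 0 + 0i)
  ## 1000 random particles against a high-precision pairwise sum
  set.seed(8)
  n <- 1000
  ps3 <- stationary_set(matrix(rnorm(3 * n), n, 3), volume = runif(n))
  ps3$M <- matrix(rnorm(3 * n), n, 3)
  ref_re <- sum(sort(ps3$volume * ps3$M[, 1]))   # better-conditioned order
  ref_im <- sum(sort(ps3$volume * ps3$M[, 2]))
  s <- sample_signal(ps3)
  expect_equal(Re(s), ref_re, tolerance = 1e-12)
  expect_equal(Im(s), ref_im, tolerance = 1e-12)
})

test_that("stationary line acquisition matches the brute-force oracle", {
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, FOVxy = 24, slab_width = 12,
                     readout_window = 1.6)
  ps <- stationary_set(disc_points(40, 8, seed = 13, z = c(-9, 9)),
                       volume = 0.5)
  for (line in list(c(0, 0), c(3, -1), c(-4, 1))) {
    ref <- brute_line(ps, p, c(-6, 6), line[1], line[2])
    st <- acq_state(ps, p, c(-6, 6), n_tr = 1)
    got <- acquire_line(st, line[1], line[2])
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("moving line acquisition matches the brute-force oracle", {
  ps <- tiny_flow_set(n_traj = 4, L = 40, Q = 2.5, d = 8)
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, FOVxy = 24, slab_width = 12,
                     readout_window = 1.6,
                     TONE = list(enabled = TRUE, span = 20))
  slab <- c(-6, 6)
  for (line in list(c(0, 0), c(2, -1))) {
    ref <- brute_line(ps, p, slab, line[1], line[2])
    st <- acq_state(ps, p, slab, n_tr = 1)
    got <- acquire_line(st, line[1], line[2])
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("chemical-shift off-resonance matches the brute-force oracle", {
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, FOVxy = 24, slab_width = 12,
                     readout_window = 1.6)
  fat <- tissue_properties(260, 80, 0.9, domega = 0.5, name = "fat")
  ps <- stationary_set(disc_points(30, 8, seed = 19, z = c(-5, 5)),
                       tissue = fat)
  ref <- brute_line(ps, p, c(-6, 6), 1, -1)
  st <- acq_state(ps, p, c(-6, 6), n_tr = 1)
  got <- acquire_line(st, 1, -1)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("an empty phantom gives a zero line and zero k-space", {
  p <- tiny_protocol(Nx = 8, Ny = 4, Nz = 2)
  ps <- stationary_set(matrix(numeric(0), 0, 3))
  st <- acq_state(ps, p, c(-8, 8), n_tr = 1)
  expect_equal(acquire_line(st, 0, 0), complex(8))
  ## zero proton density also nulls everything
  ps0 <- stationary_set(disc_points(20, 8, seed = 1),
                        tissue = tissue_properties(850, 170, 0))
  K <- simulate_slab(ps0, p, c(-8, 8))
  expect_equal(max(Mod(K$data)), 0)
})

test_that("DC line of a stationary phantom peaks at the echo centre", {
  p <- tiny_protocol(Nx = 32, Ny = 8, Nz = 4)
  ps <- stationary_set(disc_points(500, 10, seed = 3), volume = 1 / 500)
  st <- acq_state(ps, p, c(-8, 8), n_tr = 1)
  s <- acquire_line(st, 0, 0)
  expect_equal(which.max(Mod(s)), 32 / 2 + 1)
})

test_that("stationary k-space is Hermitian-symmetric in steady state", {
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, FOVxy = 24, slab_width = 12,
                     readout_window = 0.64)
  ps <- stationary_set(disc_points(300, 8, seed = 5, z = c(-6, 6)),
                       volume = 1 / 300)
  K <- simulate_slab(ps, p, c(-6, 6), n_dummy = 60)$data
  ## on-resonance the excited magnetization points along -y, a global
  ## receiver phase of -i: S(-k) = -conj(S(k)); multiplying by i makes the
  ## effective object real and the spectrum Hermitian. Residual asymmetry
  ## comes from T2 decay across the (short) readout window.
  K <- 1i * K
  err <- 0; ref <- max(Mod(K))
  for (i in 2:16) for (j in 2:8) for (l in 2:4) {
    err <- max(err, Mod(K[i, j, l] - Conj(K[18 - i, 10 - j, 6 - l])))
  }
  expect_lt(err / ref, 0.02)
})

test_that("k-space is additive over tissue components", {
  p <- tiny_protocol(Nx = 8, Ny = 4, Nz = 2)
  A <- stationary_set(disc_points(30, 8, seed = 1), volume = 0.3)
  B <- stationary_set(disc_points(30, 8, seed = 2), volume = 0.7)
  KA <- simulate_slab(A, p, c(-8, 8))$data
  KB <- simulate_slab(B, p, c(-8, 8))$data
  KAB <- simulate_slab(list(A, B), p, c(-8, 8))$data
  expect_equal(KAB, KA + KB, tolerance = 1e-12)
})

test_that("chunked acquisition equals the single-chunk result", {
  ps <- tiny_flow_set(n_traj = 8, L = 60)
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, slab_width = 16,
                     readout_window = 1.6)
  K1 <- run_chunked(ps, p, c(-8, 8), n_chunks = 1)$data
  K4 <- run_chunked(ps, p, c(-8, 8), n_chunks = 4)$data
  expect_lt(max(Mod(K1 - K4)) / max(Mod(K1)), 1e-10)
  ## a chunk count exceeding the trajectories leaves empty chunks (zero
  ## contribution) and still reproduces the result
  K12 <- run_chunked(ps, p, c(-8, 8), n_chunks = 12)$data
  expect_lt(max(Mod(K1 - K12)) / max(Mod(K1)), 1e-10)
})

test_that("slow flow converges to the frozen stationary result", {
  ps <- tiny_flow_set(n_traj = 6, L = 60, Q = 1e-7)
  p <- tiny_protocol(Nx = 8, Ny = 4, Nz = 2, slab_width = 16,
                     readout_window = 1.6)
  ## slab edges chosen off the particle lattice so boundary spins cannot
  ## flip membership between the two code paths
  slab <- c(-7.93, 8.21)
  Kmov <- simulate_slab(ps, p, slab)$data
  Kfro <- simulate_slab(freeze_particles(ps, 0), p, slab)$data
  expect_lt(max(Mod(Kmov - Kfro)) / max(Mod(Kfro)), 1e-5)
})

test_that("particles injected mid-line stay silent until the next cycle", {
  ps <- tiny_flow_set(n_traj = 2, L = 40)
  p <- tiny_protocol(Nx = 16, Ny = 8, Nz = 4, slab_width = 12,
                     readout_window = 1.6)
  ## particles born after the RF pulse of the first TR
  born_late <- -ps$tshift
  st <- acq_state(ps, p, c(-6, 6), n_tr = 1)
  s <- acquire_line(st, 0, 0)
  ## drop all future injections: identical line
  ps2 <- ps
  ps2$seedings$dt_inj <- 1e9   # no injections at all
  st2 <- acq_state(ps2, p, c(-6, 6), n_tr = 1)
  s2 <- acquire_line(st2, 0, 0)
  expect_equal(s, s2, tolerance = 1e-12)
})

test_that("per-trajectory particle count is conserved during a scan", {
  ps <- tiny_flow_set(n_traj = 4, L = 40)
  p <- tiny_protocol(Nx = 8, Ny = 4, Nz = 2, slab_width = 12)
  st <- acq_state(ps, p, c(-6, 6), n_tr = 8)
  for (r in 1:8) acquire_line(st, 0, 0)
  counts0 <- tabulate(ps$traj, 4)
  for (t in c(50, 150, 310)) {
    alive <- st$u_birth <= t & st$u_death >= t
    counts <- tabulate(st$u_traj[alive], 4)
    expect_true(all(abs(counts - counts0) <= 1))
  }
})

test_that("runtime grows about linearly with the particle count", {
  p <- tiny_protocol(Nx = 16, Ny = 4, Nz = 2, slab_width = 16,
                     readout_window = 1.6)
  times <- vapply(c(2, 4, 8), function(nt) {
    ps <- tiny_flow_set(n_traj = nt, L = 60)
    st <- acq_state(ps, p, c(-8, 8), n_tr = 8)
    system.time(for (r in 1:8) acquire_line(st, 0, 0))[["elapsed"]]
  }, numeric(1))
  ## a linear trend: quadrupling the particles must not blow up the time
  ## beyond a generous linearity margin
  expect_lt(times[3], 8 * max(times[1], 0.05))
  expect_true(all(diff(times) > -0.05))
})
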