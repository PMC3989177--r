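# Protocol validation, slab planning, phase encoding, flow compensation
# and presaturation.

test_that("protocol invariants are enforced", {
  expect_error(tof_protocol(TE = 50, TR = 40, FA = 20), "TE < TR")
  expect_error(tof_protocol(TE = 1, TR = 40, FA = 20, readout_window = 6),
               "TE too short")
  expect_error(tof_protocol(TE = 4.7, TR = 40, FA = 20, slab_width = 44,
                            slab_overlap = 44), "overlap")
  p <- tof_protocol(TE = 4.7, TR = 40, FA = 20, matrix = c(224, 160, 44),
                    FOV = c(175, 134, 144), slab_width = 44)
  ## slice thickness * Nz = slab width; dt = window / Nx
  expect_equal(p$slice_thickness * p$matrix[3], p$slab_width)
  expect_equal(p$dt, p$readout_window / 224)
})

test_that("slab planning covers the FOV with the stated overlap", {
  ## 144 mm with 44/8 slabs -> 4 slabs (44 + 3 * 36 = 152)
  pl <- plan_slabs(144, 44, 8)
  expect_equal(nrow(pl), 4)
  expect_equal(pl$z_max - pl$z_min, rep(44, 4))
  expect_equal(pl$z_min[-1] - pl$z_min[-4], rep(36, 3))
  expect_gte(pl$z_max[4] - pl$z_min[1], 144)
  ## abutting slabs at overlap 0; a single slab when it already covers
  pl0 <- plan_slabs(88, 44, 0)
  expect_equal(nrow(pl0), 2)
  expect_equal(pl0$z_min[2], pl0$z_max[1])
  expect_equal(nrow(plan_slabs(40, 44, 8)), 1)
  expect_error(plan_slabs(100, 44, 50), "overlap")
})

test_that("phase-encode phases follow the DFT convention", {
  p <- tiny_protocol(Ny = 16, Nz = 8, FOVxy = 32, slab_width = 16)
  slab <- c(-8, 8)
  ## DC line: zero phase everywhere
  set.seed(4)
  pts <- cbind(runif(5, -16, 16), runif(5, -16, 16), runif(5, -8, 8))
  expect_equal(phase_encode_offsets(p, 0, 0, pts, slab), rep(0, 5))
  ## one voxel off-centre in y at ky = 1: phase 2 pi / Ny
  vox <- c(0, 32 / 16, 0)
  expect_equal(phase_encode_offsets(p, 1, 0, vox, slab), 2 * pi / 16)
  ## periodicity: positions one FOV apart share the phase mod 2 pi
  a <- phase_encode_offsets(p, 3, 0, c(0, 5, 0), slab)
  b <- phase_encode_offsets(p, 3, 0, c(0, 5 + 32, 0), slab)
  expect_equal((b - a) / (2 * pi), round((b - a) / (2 * pi)), tolerance = 1e-9)
  expect_error(phase_encode_offsets(p, 8, 0, vox, slab), "ky")
  expect_error(phase_encode_offsets(p, 0, 4, vox, slab), "kz")
})

test_that("flow compensation nulls the first moment at the echo", {
  p <- tiny_protocol()
  rg <- readout_gradients(p)
  ## moments of the compensated prephaser match the design targets
  fcw <- flow_comp_waveform(rg$prephaser, rg$t_echo, rg$readout)
  m_base <- gradient_moments(rg$prephaser, rg$t_echo)
  m_comp <- gradient_moments(fcw, rg$t_echo)
  expect_equal(m_comp[["m0"]], m_base[["m0"]], tolerance = 1e-9)
  m_total <- gradient_moments(list(fcw, rg$readout), rg$t_echo)
  expect_lt(abs(m_total[["m1"]]), 1e-9)

  ## static particle: phase at echo identical with and without flow comp
  ph_static_base <- gradient_phase(list(rg$prephaser, rg$readout),
                                   x0 = 7, v = 0, t_end = rg$t_echo)
  ph_static_comp <- gradient_phase(list(fcw, rg$readout),
                                   x0 = 7, v = 0, t_end = rg$t_echo)
  expect_equal(ph_static_comp, ph_static_base, tolerance = 1e-6)
  expect_lt(abs(ph_static_comp), 1e-6)   # zeroth moment is nulled at echo

  ## constant-velocity particle: compensated phase < 1e-6 rad
  ph_v <- gradient_phase(list(fcw, rg$readout), x0 = 7, v = 0.1,
                         t_end = rg$t_echo, n_steps = 2e5)
  expect_lt(abs(ph_v), 1e-6)
  ## without compensation the echo phase grows linearly with velocity
  ph1 <- gradient_phase(list(rg$prephaser, rg$readout), x0 = 0, v = 0.05,
                        t_end = rg$t_echo, n_steps = 2e5)
  ph2 <- gradient_phase(list(rg$prephaser, rg$readout), x0 = 0, v = 0.10,
                        t_end = rg$t_echo, n_steps = 2e5)
  expect_gt(abs(ph1), 1e-3)
  expect_equal(ph2 / ph1, 2, tolerance = 1e-3)
  ## infeasible timing is rejected
  late <- gradient_event("x", -10, 2, rg$t_echo - 1)
  expect_error(flow_comp_waveform(late, rg$t_echo), "infeasible")
})

test_that("presaturation zeroes in-band spins; recovery follows T1", {
  pos <- rbind(c(0, 0, 30), c(0, 0, -5), c(0, 0, 55))
  ps <- stationary_set(pos)
  ps$M <- cbind(c(0.1, 0.2, 0.3), c(0, 0, 0), c(0.9, 0.8, 0.7))
  out <- presaturate(ps, band = c(25, 50), t = 0)
  expect_equal(out$M[1, ], c(0, 0, 0))       # in band
  expect_equal(out$M[2, ], ps$M[2, ])        # below band
  expect_equal(out$M[3, ], ps$M[3, ])        # above band
  ## recovery 200 ms after leaving the band, T1 = 850 ms
  rec <- relax(c(0, 0, 0), 200, tissue_properties(850, 170, 1))
  expect_equal(rec[3], 1 - exp(-200 / 850), tolerance = 1e-12)
  expect_equal(rec[3], 0.2096, tolerance = 1e-3)
})

test_that("tr_schedule is ordered, echoes at TE, spoils last", {
  p <- tiny_protocol(TE = 4.7, TR = 40)
  slab <- c(-8, 8)
  ev <- tr_schedule(p, slab, ky = 0, kz = 0)
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$time <= p$TR))
  expect_equal(ev$event[nrow(ev)], "spoil")
  ## echo centre at rf centre + TE
  expect_equal(attr(ev, "t_echo"), p$rf_duration / 2 + 4.7)
  ts <- attr(ev, "sample_times")
  expect_equal(length(ts), p$matrix[1])
  expect_equal(ts[p$matrix[1] / 2 + 1], attr(ev, "t_echo"))
  ## one line per TR: the full slab needs Ny * Nz repetitions
  lo <- line_order(p)
  expect_equal(nrow(lo), p$matrix[2] * p$matrix[3])
  expect_equal(sort(unique(lo$ky)), (-8):7)
  expect_equal(sort(unique(lo$kz)), (-4):3)
})

test_that("presat band geometry sits beyond the slab on the chosen side", {
  p <- tiny_protocol(presat = list(enabled = TRUE, side = +1, width = 40,
                                   gap = 5))
  b <- tofsim:::presat_band(p, c(-8, 8))
  expect_equal(b, c(13, 53))
  p2 <- tiny_protocol(presat = list(enabled = TRUE, side = -1, width = 40,
                                    gap = 5))
  expect_equal(tofsim:::presat_band(p2, c(-8, 8)), c(-53, -13))
})
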