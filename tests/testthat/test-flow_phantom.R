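# Geometry, laminar velocity field and trajectory integration.

test_that("geometry radius profiles match their specification", {
  g <- make_geometry("straight", 8, 207)
  expect_equal(radius_at(g, c(0, 100, 207)), rep(4, 3))

  s50 <- make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5)
  expect_equal(radius_at(s50, 103.5), 2)          # throat diameter 4 mm
  expect_equal(radius_at(s50, c(0, 207)), c(4, 4))
  s75 <- make_geometry("stenosed", 8, 207, stenosis_fraction = 0.75)
  expect_equal(radius_at(s75, 103.5), 1)          # throat diameter 2 mm

  ## radius profile is continuous and positive through the neck
  s <- seq(95, 112, by = 0.01)
  r <- radius_at(s50, s)
  expect_true(all(r > 0))
  expect_lt(max(abs(diff(r))), 0.01)
})

test_that("degenerate geometries are rejected", {
  expect_error(make_geometry("stenosed", 8, 207, stenosis_fraction = 1),
               "stenosis_fraction")
  expect_error(make_geometry("straight", -8, 207), "diameter")
  expect_error(make_geometry("ubend", 8, 100), "bend_radius")
  expect_error(make_geometry("ubend", 8, 100, bend_radius = 3), "exceed")
})

test_that("ubend centerline is continuous with the right length", {
  g <- make_geometry("ubend", 8, 100, bend_radius = 44)
  expect_equal(g$total_length, 200 + pi * 44)
  s <- seq(0, g$total_length, length.out = 2000)
  p <- centerline_point(g, s)
  steps <- sqrt(rowSums(diff(p)^2))
  ## uniform arc-length steps map to uniform space steps
  expect_lt(max(abs(steps - mean(steps))) / mean(steps), 1e-3)
  ## ends: (0,0,0) up, (2*Rb, 0, 0) down
  expect_equal(p[1, ], c(0, 0, 0))
  expect_equal(unname(p[2000, ]), c(88, 0, 0), tolerance = 1e-8)
})

test_that("lumen volume quadrature matches closed forms", {
  g <- make_geometry("straight", 8, 207)
  expect_equal(lumen_volume(g), pi * 16 * 207, tolerance = 1e-10)
  ## cosine neck has an analytic volume: R(s) = R0 (1 - f w), w = (1+cos)/2
  s50 <- make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5,
                       stenosis_extent = 10)
  f <- 0.5; e <- 10; R0 <- 4
  neck <- e * R0^2 * ((1 - f / 2)^2 + f^2 / 8)   # int (1 - f w)^2 over neck
  expect_equal(lumen_volume(s50), pi * (R0^2 * (207 - e) + neck),
               tolerance = 1e-6)
})

test_that("Poiseuille field: peak speed, no-slip, out-of-domain", {
  f <- flow_field(make_geometry("straight", 8, 207), 2.5)
  ## v_max = 2 Q / (pi R^2): 2.5 ml/s in an 8 mm tube -> 99.5 mm/s
  expect_equal(vmax_at(f, 0) * 1000, 99.47, tolerance = 1e-3)
  v <- axial_velocity(f, c(0, 0, 100))
  expect_equal(v[1:2], c(0, 0))
  expect_equal(v[3], vmax_at(f, 100))
  ## no slip at the wall
  vw <- axial_velocity(f, c(4, 0, 100))
  expect_lt(sqrt(sum(vw^2)), 1e-9)
  expect_error(axial_velocity(f, c(5, 0, 100)), "outside")
})

test_that("flux is conserved through random cross-sections", {
  for (kind in c("straight", "stenosed")) {
    geom <- if (kind == "straight") make_geometry("straight", 8, 207)
            else make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5)
    f <- flow_field(geom, 2.5)
    set.seed(7)
    svals <- runif(10, 0, 207)
    for (s in svals) {
      R <- radius_at(geom, s)
      ## integrate v(r) 2 pi r dr on a fine grid
      r <- seq(0, R, length.out = 2001)
      v <- vmax_at(f, s) * (1 - (r / R)^2)
      flux <- sum((v * 2 * pi * r)[-1] * diff(r))
      expect_lt(abs(flux - 2.5) / 2.5, 0.005)
    }
  }
})

test_that("mean speed rises by the area ratio through a 50% stenosis", {
  geom <- make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5)
  f <- flow_field(geom, 2.5)
  ## mean speed = Q / A; area ratio (R0/Rt)^2 = 4
  mean_speed <- function(s) 2.5 / (pi * radius_at(geom, s)^2)
  expect_equal(mean_speed(103.5) / mean_speed(10), 4, tolerance = 1e-12)
  ## the same holds for the centerline particle speed
  expect_equal(vmax_at(f, 103.5) / vmax_at(f, 10), 4, tolerance = 1e-12)
})

test_that("trajectories: straight-tube transit and stenosis acceleration", {
  f <- flow_field(make_geometry("straight", 8, 207), 2.5)
  tr <- integrate_trajectory(f, c(0, 0), dt_flow = 1)
  ## constant speed along a straight path
  expect_lt(diff(range(tr$speed)), 1e-12)
  expect_lt(max(abs(tr$pos[, 1:2])), 1e-12)
  ## transit time ~ L / v_max = 207 / 0.09947 ms
  expect_equal(tr$duration, 207 / vmax_at(f, 0), tolerance = 1e-3)

  fs <- flow_field(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5),
                   2.5)
  trs <- integrate_trajectory(fs, c(1, 1), dt_flow = 1)
  v <- trs$speed
  peak <- which.max(v)
  ## speed rises monotonically into the throat and relaxes after it
  expect_gt(v[peak] / v[1], 3.5)
  expect_true(all(diff(v[1:peak]) >= -1e-12))
  expect_true(all(diff(v[peak:length(v)]) <= 1e-12))
  ## seeds outside the inlet are rejected
  expect_error(integrate_trajectory(f, c(4.5, 0)), "outside")
})

test_that("trajectory speeds match the field along the path", {
  fs <- flow_field(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5),
                   2.5)
  set.seed(3)
  for (i in 1:5) {
    r <- runif(1, 0, 3.5); th <- runif(1, 0, 2 * pi)
    tr <- integrate_trajectory(fs, c(r * cos(th), r * sin(th)), dt_flow = 2)
    idx <- seq(1, nrow(tr$pos), by = 25)
    vfield <- axial_velocity(fs, tr$pos[idx, , drop = FALSE], strict = FALSE)
    speed_field <- sqrt(rowSums(vfield^2))
    vmax <- vmax_at(fs, 103.5)
    expect_lt(max(abs(tr$speed[idx] - speed_field), na.rm = TRUE) / vmax, 0.01)
  }
})

test_that("interpolate_position is exact at samples and refines correctly", {
  f <- flow_field(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.5),
                  2.5)
  tr <- integrate_trajectory(f, c(1, 0), dt_flow = 4)
  ## exact at sample times
  k <- c(1, 10, 100)
  expect_equal(interpolate_position(tr, tr$t[k]), tr$pos[k, ],
               ignore_attr = TRUE)
  ## midpoint on a straight segment
  fstr <- flow_field(make_geometry("straight", 8, 207), 2.5)
  trs <- integrate_trajectory(fstr, c(0, 0), dt_flow = 4)
  mid <- interpolate_position(trs, trs$t[5] + 2)
  expect_equal(mid, (trs$pos[5, ] + trs$pos[6, ]) / 2, ignore_attr = TRUE)
  ## refinement oracle: against a dense re-integration at dt/100
  tr_fine <- integrate_trajectory(f, c(1, 0), dt_flow = 0.04)
  set.seed(11)
  tq <- runif(20, 0, min(tr$duration, tr_fine$duration))
  for (t in tq) {
    err <- sqrt(sum((interpolate_position(tr, t) -
                     interpolate_position(tr_fine, t))^2))
    expect_lt(err, 4 * max(tr$speed) / 2)
  }
  ## out-of-span times signal an error
  expect_error(interpolate_position(tr, -5), "span")
  expect_error(interpolate_position(tr, tr$duration + 5), "span")
})
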