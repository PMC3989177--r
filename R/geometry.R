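## Parametric vessel geometries: straight tubes, cosine-tapered stenoses and
## U-bends. All lengths in mm. The centerline is parameterised by arc length
## s in [0, total_length]; straight tubes run along +z, the U-bend lies in
## the x-z plane (up the first leg, half-turn, down the return leg).

#' Create a tube geometry
#'
#' Builds a parametric vessel segment used by the flow and seeding stages.
#' Supported kinds are a straight cylinder, a cylinder with an axisymmetric
#' stenosis, and a U-bend (two parallel legs joined by a half-circle).
#'
#' The stenosis narrows the local diameter by `stenosis_fraction`: the throat
#' diameter is `(1 - stenosis_fraction) * diameter`, so a 50% stenosis halves
#' the diameter and quarters the cross-sectional area. The radius profile is
#' a C1 cosine taper over `stenosis_extent` millimetres centred at
#' `stenosis_center`.
#'
#' For `kind = "ubend"`, `length` is the length of each straight leg; the
#' total centerline length is `2 * length + pi * bend_radius`.
#'
#' @param kind one of `"straight"`, `"stenosed"`, `"ubend"`.
#' @param diameter inner diameter in mm (unstenosed).
#' @param length tube length in mm (leg length for a U-bend).
#' @param stenosis_fraction fraction of the diameter removed at the throat,
#'   in `[0, 1)`; only for `kind = "stenosed"`.
#' @param stenosis_center arc-length position of the throat centre (mm);
#'   defaults to the tube midpoint.
#' @param stenosis_extent axial extent of the cosine neck (mm).
#' @param bend_radius curvature radius of the U-bend centerline (mm).
#' @return an object of class `tube_geometry`.
#' @examples
#' g <- make_geometry("stenosed", diameter = 8, length = 207,
#'                    stenosis_fraction = 0.5)
#' radius_at(g, c(0, 103.5, 207))  # 4, 2, 4 mm
#' @export
make_geometry <- function(kind = c("straight", "stenosed", "ubend"),
                          diameter, length,
                          stenosis_fraction = 0,
                          stenosis_center = NULL,
                          stenosis_extent = 10,
                          bend_radius = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(diameter) || diameter <= 0) stopf("diameter must be > 0 (got %s)", format(diameter))
  if (!is.numeric(length) || length <= 0) stopf("length must be > 0")
  g <- list(kind = kind, diameter = diameter, length = length,
            stenosis_fraction = 0, stenosis_center = NA_real_,
            stenosis_extent = NA_real_, bend_radius = NA_real_)
  if (kind == "stenosed") {
    if (stenosis_fraction <= 0 || stenosis_fraction >= 1)
      stopf("stenosis_fraction must lie in (0, 1); %s closes or leaves the lumen intact",
            format(stenosis_fraction))
    if (is.null(stenosis_center)) stenosis_center <- length / 2
    if (stenosis_extent <= 0) stopf("stenosis_extent must be > 0")
    if (stenosis_center - stenosis_extent / 2 < 0 ||
        stenosis_center + stenosis_extent / 2 > length)
      stopf("stenosis interval [%g, %g] must lie inside [0, %g]",
            stenosis_center - stenosis_extent / 2,
            stenosis_center + stenosis_extent / 2, length)
    g$stenosis_fraction <- stenosis_fraction
    g$stenosis_center <- stenosis_center
    g$stenosis_extent <- stenosis_extent
  } else if (kind == "ubend") {
    if (is.null(bend_radius)) stopf("ubend geometry requires bend_radius")
    if (bend_radius <= diameter / 2)
      stopf("bend_radius (%g) must exceed the tube radius (%g)", bend_radius, diameter / 2)
    g$bend_radius <- bend_radius
  }
  g$total_length <- if (kind == "ubend") 2 * length + pi * bend_radius else length
  class(g) <- "tube_geometry"
  g
}

#' Local lumen radius
#'
#' Radius of the lumen at arc length `s` along the centerline (vectorised).
#' @param geom a [make_geometry()] object.
#' @param s arc length(s) in mm.
#' @return numeric vector of radii in mm.
#' @export
radius_at <- function(geom, s) {
  r0 <- geom$diameter / 2
  if (geom$kind != "stenosed") return(rep(r0, length(s)))
  w <- numeric(length(s))
  u <- (s - geom$stenosis_center) / geom$stenosis_extent  # [-1/2, 1/2] in neck
  inside <- abs(u) <= 0.5
  w[inside] <- 0.5 * (1 + cos(2 * pi * u[inside]))
  r0 * (1 - geom$stenosis_fraction * w)
}

## Centerline position, tangent and transverse frame at arc length s.
## Returns list of matrices p, tangent, n1, n2 (each length(s) x 3).
centerline_frame <- function(geom, s) {
  n <- length(s)
  p <- matrix(0, n, 3); tg <- matrix(0, n, 3)
  n1 <- matrix(0, n, 3); n2 <- matrix(0, n, 3)
  if (geom$kind != "ubend") {
    p[, 3] <- s
    tg[, 3] <- 1
    n1[, 1] <- 1
    n2[, 2] <- 1
    return(list(p = p, tangent = tg, n1 = n1, n2 = n2))
  }
  L1 <- geom$length; Rb <- geom$bend_radius
  arc_end <- L1 + pi * Rb
  seg1 <- s <= L1
  seg3 <- s >= arc_end
  seg2 <- !seg1 & !seg3
  ## first leg: up +z
  p[seg1, 3] <- s[seg1]
  tg[seg1, 3] <- 1; n1[seg1, 1] <- 1
  ## arc: half circle in x-z plane, centre (Rb, 0, L1)
  phi <- (s[seg2] - L1) / Rb
  p[seg2, 1] <- Rb * (1 - cos(phi))
  p[seg2, 3] <- L1 + Rb * sin(phi)
  tg[seg2, 1] <- sin(phi); tg[seg2, 3] <- cos(phi)
  n1[seg2, 1] <- cos(phi); n1[seg2, 3] <- -sin(phi)
  ## return leg: down -z
  p[seg3, 1] <- 2 * Rb
  p[seg3, 3] <- L1 - (s[seg3] - arc_end)
  tg[seg3, 3] <- -1; n1[seg3, 1] <- -1
  n2[, 2] <- 1
  ## keep the frame right-handed: n2 = tangent x n1
  n2[seg3, 2] <- 1   # (-z) x (-x) = +y? cross((0,0,-1),(-1,0,0)) = (0,1,0) ok
  list(p = p, tangent = tg, n1 = n1, n2 = n2)
}

#' Centerline point
#'
#' 3D position of the centerline at arc length `s` (vectorised).
#' @inheritParams radius_at
#' @return matrix `length(s) x 3` of positions (mm).
#' @export
centerline_point <- function(geom, s) centerline_frame(geom, s)$p

## Project a 3D point onto the centerline: returns list(s, r) with r the
## transverse distance. Points are in the geometry's local frame.
centerline_project <- function(geom, pts) {
  pts <- rbind(pts)
  if (geom$kind != "ubend") {
    s <- pts[, 3]
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    return(list(s = s, r = r))
  }
  L1 <- geom$length; Rb <- geom$bend_radius
  n <- nrow(pts)
  s <- numeric(n); r <- numeric(n)
  ## region split by z and by angle around the arc centre
  dx <- pts[, 1] - Rb; dz <- pts[, 3] - L1
  in_arc <- pts[, 3] > L1 & abs(atan2(dz, -dx)) <= pi   # upper half plane
  arc <- pts[, 3] > L1
  phi <- atan2(dz[arc], -dx[arc])
  phi <- pmin(pmax(phi, 0), pi)
  s[arc] <- L1 + Rb * phi
  ## radial distance in the bend plane + out-of-plane component
  rho <- sqrt(dx[arc]^2 + dz[arc]^2)
  r[arc] <- sqrt((rho - Rb)^2 + pts[arc, 2]^2)
  low <- !arc
  if (any(low)) {
    leg2 <- pts[low, 1] > Rb
    sl <- ifelse(leg2, L1 + pi * Rb + (L1 - pts[low, 3]), pts[low, 3])
    xl <- ifelse(leg2, pts[low, 1] - 2 * Rb, pts[low, 1])
    s[low] <- sl
    r[low] <- sqrt(xl^2 + pts[low, 2]^2)
  }
  list(s = s, r = r)
}

#' Lumen volume
#'
#' Volume of the lumen, `integral of pi R(s)^2 ds` over the centerline,
#' evaluated by composite Simpson quadrature.
#' @inheritParams radius_at
#' @param n number of quadrature intervals (even).
#' @return volume in mm^3.
#' @export
lumen_volume <- function(geom, n = 4096) {
  if (n %% 2 == 1) n <- n + 1
  s <- seq(0, geom$total_length, length.out = n + 1)
  f <- pi * radius_at(geom, s)^2
  h <- s[2] - s[1]
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f) * h / 3
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry: %s, d = %g mm, length = %g mm", x$kind,
              x$diameter, x$length))
  if (x$kind == "stenosed")
    cat(sprintf(", %.0f%% stenosis (throat %g mm) at s = %g mm",
                100 * x$stenosis_fraction,
                x$diameter * (1 - x$stenosis_fraction), x$stenosis_center))
  if (x$kind == "ubend")
    cat(sprintf(", bend radius %g mm", x$bend_radius))
  cat(">\n")
  invisible(x)
}
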