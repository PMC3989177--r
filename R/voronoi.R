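## Voronoi tessellation of the inlet disc. Every trajectory seed on the
## inlet cross-section owns the region of the disc nearer to it than to any
## other seed; the cell area fixes the fluid volume carried per particle on
## that trajectory. Cells are built by clipping a bounding square with the
## perpendicular-bisector half-planes of all other seeds and intersecting
## the resulting convex polygon with the disc exactly (per-edge circular
## segment integration), so the areas close to the disc area at machine
## precision.

## Clip a convex CCW polygon (n x 2 matrix) with the half-plane a.x <= b.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- poly %*% a - b
  nxt <- c(2:n, 1L)
  keep_in <- d <= 0
  out <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (keep_in[i]) out <- rbind(out, poly[i, ])
    if (xor(keep_in[i], keep_in[j])) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

## Exact area of the intersection of a convex CCW polygon with the disc of
## radius R centred at the origin. Green's-theorem walk: each directed edge
## contributes the area of triangle (O, P1, P2) clipped to the disc, with
## chord crossings handled by circular sectors.
poly_circle_area <- function(poly, R) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  total <- 0
  R2 <- R * R
  cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
  sector <- function(u, v) {
    ## signed angle sector area between rays through u and v
    R2 / 2 * atan2(cross2(u, v), sum(u * v))
  }
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1L else i + 1L, ]
    in1 <- sum(p1^2) <= R2 * (1 + 1e-12)
    in2 <- sum(p2^2) <= R2 * (1 + 1e-12)
    dp <- p2 - p1
    if (in1 && in2) {
      total <- total + cross2(p1, p2) / 2
    } else {
      ## intersections of the segment with the circle
      A <- sum(dp^2); B <- 2 * sum(p1 * dp); C <- sum(p1^2) - R2
      disc <- B * B - 4 * A * C
      ts <- numeric(0)
      if (disc > 0 && A > 0) {
        sq <- sqrt(disc)
        ts <- sort(c((-B - sq) / (2 * A), (-B + sq) / (2 * A)))
        ts <- ts[ts > 1e-12 & ts < 1 - 1e-12]
      }
      if (in1 && !in2) {
        q <- p1 + ts[1] * dp
        total <- total + cross2(p1, q) / 2 + sector(q, p2)
      } else if (!in1 && in2) {
        q <- p1 + ts[length(ts)] * dp
        total <- total + sector(p1, q) + cross2(q, p2) / 2
      } else if (length(ts) == 2L) {
        q1 <- p1 + ts[1] * dp; q2 <- p1 + ts[2] * dp
        total <- total + sector(p1, q1) + cross2(q1, q2) / 2 + sector(q2, p2)
      } else {
        total <- total + sector(p1, p2)
      }
    }
  }
  total
}

#' Voronoi cell areas on the inlet disc
#'
#' Areas of the Voronoi cells of `seed_points`, clipped to the disc of
#' radius `inlet_radius` centred at the origin. The areas sum to
#' `pi * inlet_radius^2` to near machine precision.
#'
#' @param seed_points `n x 2` matrix of seed coordinates (mm), all strictly
#'   inside the disc and pairwise distinct.
#' @param inlet_radius disc radius (mm).
#' @return numeric vector of cell areas (mm^2), one per seed.
#' @examples
#' a <- voronoi_inlet_areas(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 4)
#' sum(a) - pi * 16  # ~0
#' @export
voronoi_inlet_areas <- function(seed_points, inlet_radius) {
  pts <- rbind(seed_points)
  if (ncol(pts) != 2L) stopf("seed_points must be n x 2")
  n <- nrow(pts)
  if (n < 1L) stopf("need at least one seed point")
  rr <- sqrt(rowSums(pts^2))
  if (any(rr >= inlet_radius)) stopf("seed point(s) outside the inlet disc")
  if (n > 1L) {
    dd <- as.matrix(stats::dist(pts))
    diag(dd) <- Inf
    if (min(dd) < 1e-9) stopf("duplicate seed points")
  }
  box <- 3 * inlet_radius
  square <- rbind(c(-box, -box), c(box, -box), c(box, box), c(-box, box))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    poly <- square
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) == 0L) next
      a <- pts[j, ] - pts[i, ]
      b <- (sum(pts[j, ]^2) - sum(pts[i, ]^2)) / 2
      poly <- clip_halfplane(poly, a, b)
    }
    areas[i] <- poly_circle_area(poly, inlet_radius)
  }
  areas
}

#' Low-discrepancy inlet seed layout
#'
#' Sunflower (Fibonacci spiral) layout of `n` points on the disc of radius
#' `R`: near-uniform coverage without the clustering of pure random seeds.
#' With `jitter > 0` a small seeded random perturbation is added.
#'
#' @param n number of seeds.
#' @param R disc radius (mm).
#' @param jitter standard deviation of an optional Gaussian perturbation,
#'   as a fraction of the mean seed spacing.
#' @param seed RNG seed for the jitter.
#' @return `n x 2` matrix of coordinates.
#' @export
sunflower_points <- function(n, R, jitter = 0, seed = NULL) {
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- R * sqrt((k - 0.5) / n)
  th <- k * golden
  pts <- cbind(r * cos(th), r * sin(th))
  if (jitter > 0) {
    spacing <- R / sqrt(n)
    pts <- pts + with_seed(seed, matrix(stats::rnorm(2 * n, sd = jitter * spacing), n, 2))
    ## keep strictly inside the disc
    rr <- sqrt(rowSums(pts^2))
    bad <- rr >= R * 0.999
    if (any(bad)) pts[bad, ] <- pts[bad, ] * (R * 0.998 / rr[bad])
  }
  pts
}
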