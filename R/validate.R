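## Quantitative comparison toolkit: 3D non-local-means denoising (Gaussian
## noise approximation, valid at the SNR of the images this package
## targets), integer-voxel translation alignment, Pearson correlation with
## Fisher-z confidence intervals and RMSE after common intensity scaling.

## pad a 3D array by edge replication
pad_replicate <- function(x, r) {
  d <- dim(x)
  ix <- pmin(pmax(seq_len(d[1] + 2 * r) - r, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * r) - r, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * r) - r, 1L), d[3])
  x[ix, iy, iz, drop = FALSE]
}

## sum over the patch cube of radius pr via shift-and-add on a padded array
box_sum <- function(x, pr) {
  d <- dim(x)
  out <- array(0, d - 2L * pr)
  core <- function(arr, sh) {
    arr[pr + sh[1] + seq_len(d[1] - 2 * pr),
        pr + sh[2] + seq_len(d[2] - 2 * pr),
        pr + sh[3] + seq_len(d[3] - 2 * pr), drop = FALSE]
  }
  for (dx in -pr:pr) for (dy in -pr:pr) for (dz in -pr:pr)
    out <- out + core(x, c(dx, dy, dz))
  out
}

#' 3D non-local-means denoising
#'
#' Each voxel is replaced by a weighted mean of the other voxels in its
#' search window; the weight of a candidate voxel is
#' `exp(-d2 / h^2)` where `d2` is the squared L2 distance between the two
#' voxels' patch neighbourhoods (the centre voxel of each patch excluded).
#' Borders are handled by edge replication. `search_radius = Inf` (or a
#' radius covering the volume) gives the ideal full-image filter for tiny
#' test volumes.
#'
#' @param image 3D numeric array (or `image_volume`).
#' @param patch_radius neighbourhood radius (voxels).
#' @param search_radius search window radius (voxels); `Inf` = whole image.
#' @param h filter strength (intensity units); defaults to an estimate of
#'   the noise standard deviation from the half-difference of neighbouring
#'   voxels.
#' @return denoised array (same shape; `image_volume` in, `image_volume`
#'   out).
#' @export
nlm_denoise_3d <- function(image, patch_radius = 1L, search_radius = 5L,
                           h = NULL) {
  iv <- inherits(image, "image_volume")
  x <- if (iv) image$data else image
  if (length(dim(x)) != 3L) stopf("image must be a 3D array")
  d <- dim(x)
  pr <- as.integer(patch_radius)
  if (pr < 1L) stopf("patch_radius must be >= 1")
  if (any(d < 2L * pr + 1L)) stopf("image smaller than the patch")
  sr <- if (is.infinite(search_radius)) max(d) else as.integer(search_radius)
  if (sr < 1L) stopf("search_radius must be >= 1")
  if (is.null(h)) h <- estimate_noise_sd(x)
  if (h <= 0) stopf("h must be > 0")
  xp <- pad_replicate(x, sr + pr)
  num <- array(0, d)
  den <- array(0, d)
  centre <- function(arr, sh) {
    arr[sr + pr + sh[1] + seq_len(d[1]),
        sr + pr + sh[2] + seq_len(d[2]),
        sr + pr + sh[3] + seq_len(d[3]), drop = FALSE]
  }
  x0 <- centre(xp, c(0, 0, 0))
  for (dx in -sr:sr) for (dy in -sr:sr) for (dz in -sr:sr) {
    if (dx == 0 && dy == 0 && dz == 0) next   # "all other image pixels"
    sh <- c(dx, dy, dz)
    diff2 <- (xp - pad_replicate_shift(xp, sh))^2
    ## patch distance: box sum minus the centre-voxel term
    ds <- box_sum(diff2, pr) - centre_minus(diff2, pr)
    ## ds is on the (d + 2 sr) grid; crop to the image
    d2 <- ds[sr + seq_len(d[1]), sr + seq_len(d[2]), sr + seq_len(d[3]),
             drop = FALSE]
    w <- exp(-d2 / h^2)
    num <- num + w * centre(xp, sh)
    den <- den + w
  }
  out <- num / den
  ## at strong edges every candidate weight can underflow to zero; such
  ## voxels keep their original value (no admissible average exists)
  bad <- den == 0 | !is.finite(out)
  out[bad] <- x[bad]
  if (iv) { image$data <- out; image } else out
}

## shift a padded array by sh with edge clamping (stays on the same grid)
pad_replicate_shift <- function(xp, sh) {
  d <- dim(xp)
  ix <- pmin(pmax(seq_len(d[1]) + sh[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + sh[2], 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + sh[3], 1L), d[3])
  xp[ix, iy, iz, drop = FALSE]
}

## the centre term of the patch sum (the excluded voxel pair)
centre_minus <- function(diff2, pr) {
  d <- dim(diff2)
  diff2[pr + seq_len(d[1] - 2 * pr), pr + seq_len(d[2] - 2 * pr),
        pr + seq_len(d[3] - 2 * pr), drop = FALSE]
}

#' Estimate the noise standard deviation of an image
#'
#' Robust pseudo-residual estimate: median absolute deviation of
#' neighbouring-voxel half-differences along the first axis.
#' @param x 3D array.
#' @return scalar sigma estimate.
#' @export
estimate_noise_sd <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  dif <- (x[-1, , , drop = FALSE] - x[-dim(x)[1], , , drop = FALSE]) / sqrt(2)
  stats::mad(as.numeric(dif))
}

#' Signal-to-noise ratio from two volumes of interest
#'
#' `mean(signal VOI) / sd(background VOI)`. When the magnitude background
#' is Rayleigh rather than Gaussian, `rayleigh_correct = TRUE` rescales the
#' background sd by `1/sqrt(2 - pi/2)` to the underlying Gaussian sigma.
#' A warning is issued below SNR 3, where the Gaussian approximation of
#' Rician noise breaks down.
#'
#' @param image 3D array or `image_volume`.
#' @param signal_voi,background_voi logical masks or index lists
#'   `list(i, j, k)` of ranges.
#' @param rayleigh_correct apply the Rayleigh-to-Gaussian sd correction.
#' @return SNR estimate (scalar).
#' @export
estimate_snr <- function(image, signal_voi, background_voi,
                         rayleigh_correct = FALSE) {
  x <- if (inherits(image, "image_volume")) image$data else image
  sig <- extract_voi(x, signal_voi)
  bg <- extract_voi(x, background_voi)
  if (length(sig) == 0 || length(bg) == 0) stopf("empty VOI")
  s <- stats::sd(bg)
  if (rayleigh_correct) s <- s / sqrt(2 - pi / 2)
  if (s == 0) stopf("background VOI has zero variance; SNR undefined")
  snr <- mean(sig) / s
  if (snr < 3)
    warnf("SNR = %.2f < 3: Gaussian approximation of the Rician noise is poor", snr)
  snr
}

extract_voi <- function(x, voi) {
  if (is.logical(voi)) return(x[voi])
  if (is.list(voi)) return(as.numeric(x[voi[[1]], voi[[2]], voi[[3]]]))
  stopf("VOI must be a logical mask or list of index ranges")
}

#' Integer-shift translation alignment
#'
#' Finds the integer-voxel shift of `moving` (within `+/- max_shift` on
#' each axis) that maximises the normalised cross-correlation with `fixed`
#' over the overlapping region, and applies it (zero fill outside).
#'
#' @param moving,fixed 3D arrays (or `image_volume`s) on the same voxel
#'   grid.
#' @param max_shift maximum shift per axis, voxels.
#' @return list `(shift, aligned, ncc)`.
#' @export
align_translation <- function(moving, fixed, max_shift = 3L) {
  mv <- if (inherits(moving, "image_volume")) moving$data else moving
  fx <- if (inherits(fixed, "image_volume")) fixed$data else fixed
  if (!all(dim(mv) == dim(fx))) stopf("images must share dimensions")
  if (stats::sd(mv) == 0 || stats::sd(fx) == 0)
    stopf("degenerate (constant) image")
  d <- dim(mv)
  best <- c(0L, 0L, 0L); best_ncc <- -Inf
  rng <- -max_shift:max_shift
  for (sx in rng) for (sy in rng) for (sz in rng) {
    i1 <- max(1, 1 + sx):min(d[1], d[1] + sx)
    j1 <- max(1, 1 + sy):min(d[2], d[2] + sy)
    k1 <- max(1, 1 + sz):min(d[3], d[3] + sz)
    a <- fx[i1, j1, k1]
    b <- mv[i1 - sx, j1 - sy, k1 - sz]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ncc <- stats::cor(as.numeric(a), as.numeric(b))
    if (ncc > best_ncc) { best_ncc <- ncc; best <- c(sx, sy, sz) }
  }
  if (any(abs(best) == max_shift))
    warnf("best shift (%d, %d, %d) lies on the search boundary; increase max_shift",
          best[1], best[2], best[3])
  aligned <- array(0, d)
  i1 <- max(1, 1 + best[1]):min(d[1], d[1] + best[1])
  j1 <- max(1, 1 + best[2]):min(d[2], d[2] + best[2])
  k1 <- max(1, 1 + best[3]):min(d[3], d[3] + best[3])
  aligned[i1, j1, k1] <- mv[i1 - best[1], j1 - best[2], k1 - best[3]]
  list(shift = best, aligned = aligned, ncc = best_ncc)
}

#' Compare two volumes of interest
#'
#' Pearson correlation over the VOI voxels with its 95% confidence
#' interval by the Fisher z-transform, and the RMSE after min-max scaling
#' both VOIs to `[0, 1]` (a common intensity range).
#'
#' @param imageA,imageB 3D arrays or `image_volume`s of equal dimensions.
#' @param voi optional logical mask or `list(i, j, k)` index ranges;
#'   default: the whole volume.
#' @param conf confidence level (default 0.95).
#' @return object of class `comparison_report`: fields `r`, `ci_lower`,
#'   `ci_upper`, `rmse`, `n`.
#' @export
compare_vois <- function(imageA, imageB, voi = NULL, conf = 0.95) {
  a <- if (inherits(imageA, "image_volume")) imageA$data else imageA
  b <- if (inherits(imageB, "image_volume")) imageB$data else imageB
  if (!all(dim(a) == dim(b))) stopf("images must share dimensions")
  if (!is.null(voi)) { a <- extract_voi(a, voi); b <- extract_voi(b, voi) }
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("constant VOI: correlation undefined")
  r <- stats::cor(a, b)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- zcrit / sqrt(n - 3)
  ci <- tanh(c(z - hw, z + hw))
  scale01 <- function(x) (x - min(x)) / (max(x) - min(x))
  rmse <- sqrt(mean((scale01(a) - scale01(b))^2))
  structure(list(r = r, ci_lower = ci[1], ci_upper = ci[2],
                 rmse = rmse, n = n, conf = conf),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Correlation coefficient  Lower bound  Upper bound  RMS error\n"))
  cat(sprintf("%22.4f  %11.4f  %11.4f  %9.4f   (n = %d, %.0f%% CI)\n",
              x$r, x$ci_lower, x$ci_upper, x$rmse, x$n, 100 * x$conf))
  invisible(x)
}

#' @rdname compare_vois
#' @param x a `comparison_report`.
#' @export
as_report_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
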