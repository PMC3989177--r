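## K-space to magnitude images. K-space arrays are stored centred (DC at
## index floor(N/2)+1 on every axis); reconstruction is
## magnitude(fftshift(IFFT(ifftshift(K)))) with voxel j (0-based) at
## position (j - N/2) * FOV / N along each axis. Optional separable
## low-pass filtering on the phase-encode axes, zero padding (Fourier/sinc
## interpolation) and complex Gaussian k-space noise.

as_kspace <- function(k) {
  if (inherits(k, "kspace_volume")) k
  else structure(list(data = k, protocol = NULL, slab = NULL),
                 class = "kspace_volume")
}

## Tukey (tapered cosine) window of length n, taper fraction a in [0, 1];
## a = 0 is rectangular, a = 1 the Hann window. Unity over the plateau, so
## the DC gain of a centred window is exactly 1.
tukey_window <- function(n, a = 0.5) {
  if (a < 0 || a > 1) stopf("Tukey taper fraction must be in [0, 1]")
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (a > 0) {
    lo <- x < a / 2
    hi <- x > 1 - a / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / a - 2 / a + 1)))
  }
  w
}

#' Low-pass filter raw k-space
#'
#' Element-wise multiplication by a separable window on the phase-encode
#' axes, attenuating the high spatial frequencies where pulsatile/flow
#' phase mismapping ghosts live. The window has unit DC gain.
#'
#' @param k a `kspace_volume` or complex array (centred k-space).
#' @param window `"tukey"` (tapered cosine) or `"hann"`.
#' @param alpha Tukey taper fraction in `[0, 1]`.
#' @param axes axes to filter (2 = phase encode, 3 = slice encode).
#' @return same class as `k`.
#' @export
lowpass_filter <- function(k, window = c("tukey", "hann"), alpha = 0.5,
                           axes = c(2L, 3L)) {
  window <- match.arg(window)
  kv <- as_kspace(k)
  d <- dim(kv$data)
  for (ax in axes) {
    n <- d[ax]
    w <- switch(window,
                tukey = tukey_window(n, alpha),
                hann = tukey_window(n, 1))
    ## centre the window on the DC index
    dc <- floor(n / 2) + 1L
    w <- w / w[dc]
    shape <- rep(1L, length(d)); shape[ax] <- n
    kv$data <- kv$data * array(rep(w, each = prod(d[seq_len(ax - 1L)])), d)
  }
  if (inherits(k, "kspace_volume")) kv else kv$data
}

#' Zero-pad k-space
#'
#' Embeds the measured k-space centrally in a larger grid (null padding),
#' keeping DC at the centred-grid DC index. The reconstructed image is the
#' sinc (Fourier) interpolation of the original on a finer voxel grid.
#'
#' @param k a `kspace_volume` or complex array.
#' @param target integer target dimensions (length 1 recycled, or one per
#'   axis; must be `>=` the source dimensions).
#' @return same class as `k`.
#' @export
zero_pad <- function(k, target) {
  kv <- as_kspace(k)
  d <- dim(kv$data)
  target <- as.integer(rep_len(target, length(d)))
  if (any(target < d)) stopf("target matrix smaller than source")
  if (all(target == d)) return(k)
  out <- array(0 + 0i, target)
  off <- floor(target / 2) - floor(d / 2)   # keeps the DC index aligned
  idx <- lapply(seq_along(d), function(i) off[i] + seq_len(d[i]))
  out[idx[[1]], idx[[2]], idx[[3]]] <- kv$data
  kv$data <- out
  if (inherits(k, "kspace_volume")) kv else kv$data
}

#' Reconstruct a magnitude image
#'
#' Centred inverse FFT of the (optionally filtered / zero-padded) k-space
#' followed by the complex magnitude.
#'
#' @param k a `kspace_volume` or complex array.
#' @param recon_matrix optional in-plane zero-pad target (e.g. 256): pads
#'   axes 1-2 before transforming.
#' @return an `image_volume`: real array with voxel `spacing` (mm, when
#'   the protocol is known) and the axial origin of the slab.
#' @export
reconstruct_magnitude <- function(k, recon_matrix = NULL) {
  kv <- as_kspace(k)
  if (!is.null(recon_matrix)) {
    d <- dim(kv$data)
    kv <- as_kspace(zero_pad(kv, c(rep(recon_matrix, 2), d[3])))
  }
  K <- ifftshift(kv$data)
  img <- fft(K, inverse = TRUE) / length(K)
  img <- Mod(fftshift(img))
  spacing <- NULL; origin <- c(0, 0, 0)
  if (!is.null(kv$protocol)) {
    p <- kv$protocol
    spacing <- c(p$FOV[1] / dim(img)[1], p$FOV[2] / dim(img)[2],
                 p$slab_width / dim(img)[3])
    if (!is.null(kv$slab)) origin <- c(0, 0, mean(kv$slab))
  }
  structure(list(data = img, spacing = spacing, origin = origin,
                 protocol = kv$protocol, slab = kv$slab),
            class = "image_volume")
}

#' Voxel-centre coordinates of an image axis
#'
#' @param image an `image_volume`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of coordinates (mm).
#' @export
voxel_coords <- function(image, axis) {
  n <- dim(image$data)[axis]
  sp <- if (!is.null(image$spacing)) image$spacing[axis] else 1
  ((0:(n - 1)) - n %/% 2) * sp + image$origin[axis]
}

#' Composite MOTSA slabs into one volume
#'
#' Stacks the reconstructed slab images along z on a global slice grid
#' (spacing = slice thickness, starting at the first slab's lower edge).
#' In `"discard"` mode every output slice is taken from the single slab
#' whose centre it lies deepest inside (so each adjoining slab
#' effectively loses half of the overlap and boundary slices come from
#' exactly one slab); `"max"` keeps the voxelwise maximum over all
#' covering slabs. Slabs whose slice grids are mutually shifted (overlap
#' not an integer number of slices) are placed by nearest slice.
#'
#' @param slab_images list of `image_volume`s, in ascending-slab order.
#' @param plan the [plan_slabs()] used for the acquisition.
#' @param mode `"discard"` or `"max"`.
#' @return an `image_volume` spanning the union of the slabs.
#' @export
composite_motsa <- function(slab_images, plan, mode = c("discard", "max")) {
  mode <- match.arg(mode)
  n <- length(slab_images)
  if (n != nrow(plan)) stopf("plan has %d slabs but %d images given", nrow(plan), n)
  d1 <- dim(slab_images[[1]]$data)
  for (im in slab_images)
    if (!all(dim(im$data)[1:2] == d1[1:2]))
      stopf("slab images have inconsistent in-plane matrices")
  nz <- d1[3]
  th <- attr(plan, "slab_width") / nz
  z0 <- plan$z_min[1]
  total <- as.integer(round((max(plan$z_max) - z0) / th))
  out <- array(0, c(d1[1], d1[2], total))
  zc <- z0 + (seq_len(total) - 0.5) * th
  for (k in seq_len(total)) {
    covering <- which(plan$z_min <= zc[k] + 1e-9 & plan$z_max >= zc[k] - 1e-9)
    if (length(covering) == 0L) next
    src_slice <- function(i) {
      min(max(as.integer(round((zc[k] - plan$z_min[i]) / th + 0.5)), 1L), nz)
    }
    if (mode == "max") {
      acc <- slab_images[[covering[1]]]$data[, , src_slice(covering[1])]
      for (i in covering[-1])
        acc <- pmax(acc, slab_images[[i]]$data[, , src_slice(i)])
      out[, , k] <- acc
    } else {
      ## deepest slab wins: maximise the distance to the nearest slab edge
      depth <- pmin(zc[k] - plan$z_min[covering], plan$z_max[covering] - zc[k])
      i <- covering[which.max(depth)]
      out[, , k] <- slab_images[[i]]$data[, , src_slice(i)]
    }
  }
  sp <- slab_images[[1]]$spacing
  structure(list(data = out,
                 spacing = if (!is.null(sp)) c(sp[1:2], th) else NULL,
                 origin = c(0, 0, z0 + total * th / 2),
                 protocol = slab_images[[1]]$protocol, slab = NULL),
            class = "image_volume")
}

#' Add complex Gaussian noise to k-space
#'
#' White Gaussian noise added independently to the real and imaginary
#' channels of the raw data; the magnitude-image background becomes
#' Rayleigh distributed (mean `sigma * sqrt(pi/2) / sqrt(N)` relative to
#' the transform normalisation).
#'
#' @param k a `kspace_volume` or complex array.
#' @param sigma noise standard deviation per channel (k-space units).
#' @param seed RNG seed (reproducible noise).
#' @return same class as `k`.
#' @export
add_kspace_noise <- function(k, sigma, seed = NULL) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(k)
  kv <- as_kspace(k)
  n <- length(kv$data)
  noise <- with_seed(seed, complex(real = stats::rnorm(n, sd = sigma),
                                   imaginary = stats::rnorm(n, sd = sigma)))
  kv$data <- kv$data + array(noise, dim(kv$data))
  if (inherits(k, "kspace_volume")) kv else kv$data
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- if (is.null(x$spacing)) "unknown spacing"
        else sprintf("%.3g x %.3g x %.3g mm voxels", x$spacing[1], x$spacing[2], x$spacing[3])
  cat(sprintf("<image_volume: %d x %d x %d, %s>\n", d[1], d[2], d[3], sp))
  invisible(x)
}

#' Write an image volume to NIfTI
#'
#' @param image an `image_volume`.
#' @param path output file (`.nii` / `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_image_nifti <- function(image, path) {
  sp <- image$spacing %||% c(1, 1, 1)
  RNifti::writeNifti(RNifti::asNifti(image$data, pixdim = sp), path)
  invisible(path)
}
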