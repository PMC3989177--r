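## Bundled digital phantoms and acquisition presets mirroring the
## flow-calibration phantom set this simulator was validated on: straight
## 207-mm channels of 8 and 5 mm diameter, 75% and 50% diameter stenoses,
## and an 8-mm U-bend of 44 mm curvature radius, imaged with four
## flow-rate / protocol combinations at 1.5 T.

#' Blood-mimicking fluid properties
#'
#' Glycerol/water blood-mimicking fluid at 1.5 T: relative proton density
#' 1.00, T1 = 850 ms, T2 = 170 ms (density 1020 kg/m^3 and viscosity
#' 4.1 mPa s carried as metadata).
#' @return a [tissue_properties()] object.
#' @export
make_bmf <- function() {
  tissue_properties(T1 = 850, T2 = 170, rho = 1.00, domega = 0, name = "BMF",
                    density_kg_m3 = 1020, viscosity_mPa_s = 4.1)
}

#' Bundled digital phantoms
#'
#' @param name one of:
#'   * `"four_tube"`: three 8-mm and one 5-mm straight channels of 207 mm
#'     (channel 1 with a 75% and channel 3 with a 50% diameter stenosis),
#'     centres 25 mm apart;
#'   * `"ubend"`: an 8-mm channel with two parallel legs joined by a
#'     half-circle of 44 mm curvature radius;
#'   * `"stenosis50"`, `"stenosis75"`: single stenosed 8-mm channels.
#' @param flow_rate volumetric rate per channel, mm^3/ms (= ml/s).
#' @param ubend_leg leg length of the U-bend channel, mm.
#' @return an object of class `phantom`: list of channels, each with a
#'   geometry, an in-plane `center`, an axial origin and a flow direction.
#' @export
make_phantom <- function(name = c("four_tube", "ubend", "stenosis50",
                                  "stenosis75"),
                         flow_rate = 2.5, ubend_leg = 160) {
  name <- match.arg(name)
  chan <- function(geom, center, direction = 1) {
    z0 <- -direction * geom$total_length / 2
    list(geometry = geom, center = center, z0 = z0,
         direction = direction, flow_rate = flow_rate)
  }
  channels <- switch(name,
    four_tube = list(
      chan(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.75),
           c(-37.5, 0)),
      chan(make_geometry("straight", 8, 207), c(-12.5, 0)),
      chan(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.50),
           c(12.5, 0)),
      chan(make_geometry("straight", 5, 207), c(37.5, 0))
    ),
    ubend = list(
      chan(make_geometry("ubend", 8, ubend_leg, bend_radius = 44),
           c(-44, 0))
    ),
    stenosis50 = list(
      chan(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.50),
           c(0, 0))
    ),
    stenosis75 = list(
      chan(make_geometry("stenosed", 8, 207, stenosis_fraction = 0.75),
           c(0, 0))
    ))
  structure(list(name = name, channels = channels), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s': %d channel(s)>\n", x$name, length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  - %s d=%g mm at (%g, %g), flow %+g ml/s\n",
                ch$geometry$kind, ch$geometry$diameter,
                ch$center[1], ch$center[2],
                ch$direction * ch$flow_rate))
  invisible(x)
}

#' Study presets
#'
#' The four validated flow-rate / protocol combinations:
#'
#' | Study | Q (ml/s) | TE/TR/FA | slabs (mm) | FOV x/y/z (mm) |
#' |-------|----------|----------------|-------|-----------------|
#' | 1 | 2.5 | 4.7/40/20 deg | 44/8 | 175/134/144 |
#' | 2 | 2.5 | 4.7/40/15 deg | 44/8 | 175/134/144 |
#' | 3 | 4.6 | 4.6/27/15 deg | 44/8 | 175/134/224 |
#' | 4 | 10  | 4.6/27/15 deg | 25/5 | 175/134/245 |
#'
#' All use MOTSA + TONE + presaturation + flow compensation at 1.5 T,
#' in-plane sampling 224 x 160, 1-mm slices, 256 zero-padded
#' reconstruction.
#'
#' @param study_id 1 to 4.
#' @param scale resolution/particle scale factor: the acquisition matrix
#'   and trajectory count are multiplied by `scale` (physics parameters
#'   are untouched; slice thickness grows accordingly).
#' @param phantom_name phantom to pair with the protocol.
#' @return object of class `study_preset` with elements `phantom`,
#'   `fluid`, `flow_rate`, `protocol`, `n_trajectories`,
#'   `linear_density`, `scale`.
#' @export
make_study <- function(study_id, scale = 1, phantom_name = "four_tube") {
  if (!study_id %in% 1:4) stopf("unknown study id %s", format(study_id))
  tab <- list(
    list(Q = 2.5, TE = 4.7, TR = 40, FA = 20, slab = 44, ov = 8, FOVz = 144),
    list(Q = 2.5, TE = 4.7, TR = 40, FA = 15, slab = 44, ov = 8, FOVz = 144),
    list(Q = 4.6, TE = 4.6, TR = 27, FA = 15, slab = 44, ov = 8, FOVz = 224),
    list(Q = 10,  TE = 4.6, TR = 27, FA = 15, slab = 25, ov = 5, FOVz = 245)
  )[[study_id]]
  Nx <- max(8L, round(224 * scale)); Ny <- max(8L, round(160 * scale))
  Nz <- max(2L, round(tab$slab * scale))  # 1-mm slices at scale = 1
  protocol <- tof_protocol(
    TE = tab$TE, TR = tab$TR, FA = tab$FA,
    matrix = c(Nx, Ny, Nz),
    FOV = c(175, 134, tab$FOVz),
    slab_width = tab$slab, slab_overlap = tab$ov,
    TONE = list(enabled = TRUE, span = 20),
    presat = list(enabled = TRUE, side = +1, width = 40, gap = 5),
    flow_comp = c(x = TRUE, y = TRUE, z = TRUE),
    B0 = 1.5, recon_matrix = 256)
  structure(list(study_id = study_id,
                 phantom = make_phantom(phantom_name, flow_rate = tab$Q),
                 fluid = make_bmf(),
                 flow_rate = tab$Q,
                 protocol = protocol,
                 n_trajectories = max(4L, round(256 * scale)),
                 linear_density = 3,
                 scale = scale),
            class = "study_preset")
}

#' @export
print.study_preset <- function(x, ...) {
  cat(sprintf("<study_preset %d (scale %g): Q = %g ml/s, %d trajectories/tube>\n",
              x$study_id, x$scale, x$flow_rate, x$n_trajectories))
  print(x$protocol)
  invisible(x)
}

#' Build the particle components of a phantom
#'
#' Traces trajectories, tessellates the inlets, and populates every
#' channel of a phantom with volume-weighted particles; one flowing
#' `particle_set` per channel, placed into scanner coordinates.
#'
#' @param phantom a [make_phantom()] object.
#' @param fluid the flowing [tissue_properties()].
#' @param n_trajectories trajectories per channel.
#' @param linear_density particles per mm of vessel length per trajectory.
#' @param step_length tracer arc step, mm.
#' @param jitter,seed inlet-seed jitter (fraction of spacing) and RNG
#'   seed.
#' @return list of flowing `particle_set`s (one per channel).
#' @export
build_phantom_particles <- function(phantom, fluid = make_bmf(),
                                    n_trajectories = 256,
                                    linear_density = 3,
                                    step_length = 0.5,
                                    jitter = 0, seed = NULL) {
  out <- vector("list", length(phantom$channels))
  for (i in seq_along(phantom$channels)) {
    ch <- phantom$channels[[i]]
    field <- flow_field(ch$geometry, ch$flow_rate)
    R0 <- radius_at(ch$geometry, 0)
    ip <- sunflower_points(n_trajectories, R0 * 0.999, jitter = jitter,
                           seed = if (is.null(seed)) NULL else seed + i)
    bundle <- trace_trajectories(field, ip, step_length = step_length)
    sd <- seed_trajectories(bundle, linear_density, inlet_radius = R0)
    ps <- populate(sd, bundle, fluid)
    attr(ps, "transform") <- list(origin = c(ch$center[1], ch$center[2], ch$z0),
                                  zsign = ch$direction)
    attr(ps, "flow_sign") <- ch$direction
    out[[i]] <- ps
  }
  out
}

#' Lumen mask of a phantom on an image grid
#'
#' Logical array marking voxels whose centres lie inside any channel
#' lumen.
#' @param phantom a [make_phantom()] object.
#' @param image an `image_volume` (for its grid), or a list with `dim`,
#'   `spacing`, `origin`.
#' @param channel optional channel index to restrict the mask to.
#' @return logical array of the image dimensions.
#' @export
lumen_mask <- function(phantom, image, channel = NULL) {
  xs <- voxel_coords(image, 1); ys <- voxel_coords(image, 2)
  zs <- voxel_coords(image, 3)
  d <- dim(image$data)
  pts <- cbind(rep(xs, times = d[2] * d[3]),
               rep(rep(ys, each = d[1]), times = d[3]),
               rep(zs, each = d[1] * d[2]))
  mask <- rep(FALSE, nrow(pts))
  chans <- if (is.null(channel)) phantom$channels else phantom$channels[channel]
  for (ch in chans) {
    local <- cbind(pts[, 1] - ch$center[1], pts[, 2] - ch$center[2],
                   (pts[, 3] - ch$z0) / ch$direction)
    pr <- centerline_project(ch$geometry, local)
    ok <- pr$s >= 0 & pr$s <= ch$geometry$total_length
    mask <- mask | (ok & pr$r <= radius_at(ch$geometry, pr$s))
  }
  array(mask, d)
}

## ---- YAML serialization ---------------------------------------------------

geometry_to_list <- function(g) {
  keep <- c("kind", "diameter", "length", "stenosis_fraction",
            "stenosis_center", "stenosis_extent", "bend_radius")
  out <- unclass(g)[keep]
  out[!vapply(out, function(v) is.null(v) || all(is.na(v)), logical(1))]
}

geometry_from_list <- function(l) {
  do.call(make_geometry, l)
}

#' Serialize / restore a phantom as YAML
#'
#' @param phantom a [make_phantom()] object.
#' @param path file path.
#' @return `write_phantom_yaml` returns the path invisibly;
#'   `read_phantom_yaml` the restored `phantom`.
#' @export
write_phantom_yaml <- function(phantom, path) {
  chans <- lapply(phantom$channels, function(ch) {
    list(geometry = geometry_to_list(ch$geometry),
         center = as.numeric(ch$center), z0 = ch$z0,
         direction = ch$direction, flow_rate = ch$flow_rate)
  })
  yaml::write_yaml(list(name = phantom$name, channels = chans), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  channels <- lapply(l$channels, function(ch) {
    list(geometry = geometry_from_list(ch$geometry),
         center = as.numeric(ch$center), z0 = ch$z0,
         direction = ch$direction, flow_rate = ch$flow_rate)
  })
  structure(list(name = l$name, channels = channels), class = "phantom")
}

#' Serialize / restore a protocol as YAML
#'
#' @param protocol a [tof_protocol()].
#' @param path file path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  l <- unclass(protocol)
  l$FA <- rad2deg(l$FA)
  l$TONE$span <- rad2deg(l$TONE$span)
  l$flow_comp <- as.list(l$flow_comp)
  yaml::write_yaml(l, path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  tof_protocol(TE = l$TE, TR = l$TR, FA = l$FA,
               matrix = unlist(l$matrix), FOV = unlist(l$FOV),
               slab_width = l$slab_width, slab_overlap = l$slab_overlap,
               readout_window = l$readout_window,
               rf_duration = l$rf_duration, rf_substeps = l$rf_substeps,
               TONE = l$TONE,
               presat = l$presat,
               flow_comp = c(x = isTRUE(l$flow_comp$x),
                             y = isTRUE(l$flow_comp$y),
                             z = isTRUE(l$flow_comp$z)),
               B0 = l$B0, recon_matrix = l$recon_matrix,
               line_order = l$line_order)
}
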