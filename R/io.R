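## Columnar text interfaces between the pipeline stages: the trajectory
## table (the formal hand-off from the flow stage to the MR stage),
## particle snapshots for debugging/fixtures, and raw k-space dumps.

#' Write / read a trajectory bundle as a columnar table
#'
#' One row per flow sample: `id, t, x, y, z, speed` (ms / mm / mm/ms),
#' plus per-trajectory metadata (`dt_flow`, inlet point, fractional
#' radius) in commented header lines. This table is the formal interface
#' between the flow stage and the MR stage.
#'
#' @param trajectories a trajectory bundle.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ir <- attr(trajectories, "inlet_radius")
  writeLines(sprintf("# tofsim trajectories: n=%d inlet_radius=%.17g",
                     length(trajectories), ir %||% NA_real_), con)
  for (tr in trajectories)
    writeLines(sprintf("# traj id=%d dt_flow=%.17g u=%.17g v=%.17g r_frac=%.17g",
                       tr$id, tr$dt_flow, tr$inlet_point[1],
                       tr$inlet_point[2], tr$r_frac), con)
  writeLines("id,t,x,y,z,speed", con)
  for (tr in trajectories) {
    dat <- cbind(tr$id, tr$t, tr$pos, tr$speed)
    utils::write.table(format(dat, digits = 15, trim = TRUE, scientific = NA),
                       con, sep = ",", col.names = FALSE, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# traj ", lines, value = TRUE)
  meta <- lapply(hdr, function(l) {
    kv <- regmatches(l, gregexpr("[a-z_]+=[-0-9.eE+]+", l))[[1]]
    vals <- as.numeric(sub(".*=", "", kv))
    names(vals) <- sub("=.*", "", kv)
    vals
  })
  inlet_line <- grep("^# tofsim trajectories", lines, value = TRUE)
  ir <- as.numeric(sub(".*inlet_radius=", "", inlet_line))
  dat <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  out <- lapply(meta, function(mv) {
    rows <- dat[dat$id == mv[["id"]], , drop = FALSE]
    n <- nrow(rows)
    tr <- list(id = as.integer(mv[["id"]]), t = rows$t,
               s = NULL,
               pos = cbind(rows$x, rows$y, rows$z),
               speed = rows$speed,
               dt_flow = mv[["dt_flow"]],
               inlet_point = c(mv[["u"]], mv[["v"]]),
               r_frac = mv[["r_frac"]],
               duration = rows$t[n])
    class(tr) <- "trajectory"
    tr
  })
  class(out) <- "trajectory_bundle"
  attr(out, "inlet_radius") <- ir
  out
}

#' Export a particle snapshot
#'
#' Positions and magnetization of all particles alive at time `t` as a
#' CSV table: `label, t, x, y, z, Mx, My, Mz, volume, tissue`.
#'
#' @param particles a `particle_set`.
#' @param t snapshot time, ms.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_particles_csv <- function(particles, t, path) {
  alive <- particles_alive(particles, t)
  pos <- particle_positions(particles, t)
  df <- data.frame(label = particles$label[alive], t = t,
                   x = pos[alive, 1], y = pos[alive, 2], z = pos[alive, 3],
                   Mx = particles$M[alive, 1], My = particles$M[alive, 2],
                   Mz = particles$M[alive, 3],
                   volume = particles$volume[alive],
                   tissue = particles$tissues[[1]]$name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dump / load raw k-space as interleaved float32
#'
#' Binary dump of the complex samples in array order (real, imaginary
#' interleaved, little-endian single precision) with the dimensions in a
#' sidecar `.dims` text file.
#'
#' @param k a `kspace_volume` or complex array.
#' @param path output path (the sidecar gets `.dims` appended).
#' @return the path, invisibly.
#' @export
write_kspace_raw <- function(k, path) {
  kv <- as_kspace(k)
  re <- Re(kv$data); im <- Im(kv$data)
  v <- numeric(2 * length(re))
  v[seq(1, length(v), 2)] <- as.vector(re)
  v[seq(2, length(v), 2)] <- as.vector(im)
  writeBin(v, path, size = 4L, endian = "little")
  writeLines(paste(dim(kv$data), collapse = " "), paste0(path, ".dims"))
  invisible(path)
}

#' @rdname write_kspace_raw
#' @export
read_kspace_raw <- function(path) {
  d <- as.integer(strsplit(readLines(paste0(path, ".dims")), " ")[[1]])
  n <- prod(d)
  v <- readBin(path, "numeric", n = 2L * n, size = 4L, endian = "little")
  arr <- array(complex(real = v[seq(1, 2 * n, 2)],
                       imaginary = v[seq(2, 2 * n, 2)]), d)
  structure(list(data = arr, protocol = NULL, slab = NULL),
            class = "kspace_volume")
}
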