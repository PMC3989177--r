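## Config-driven end-to-end runs: preset (or explicit phantom + protocol)
## -> trajectories -> seeding -> per-slab k-space synthesis -> magnitude
## reconstruction -> MOTSA compositing -> artifacts (NIfTI volume, JSON
## summary, log), with full provenance (config hash + seed) embedded.

#' Run a complete simulation study
#'
#' @param config a list (or path to a YAML file) with entries:
#'   * `study`, `scale`: preset selection (see [make_study()]); or
#'     `phantom` (a `phantom` or YAML path) and `protocol` (a
#'     `tof_protocol` or YAML path);
#'   * `phantom_name`: preset phantom (default `"four_tube"`);
#'   * `n_trajectories`, `linear_density`: seeding overrides;
#'   * `seed`: RNG seed (default 1);
#'   * `n_chunks`: trajectory chunks per channel (default 1);
#'   * `n_dummy`: dummy TRs before acquisition (default 0);
#'   * `slabs`: indices of the slab plan to simulate (default all);
#'   * `noise_sigma`, `filter_alpha`: optional k-space noise / Tukey
#'     filter;
#'   * `stationary`: optional list `(T1, T2, rho, density)` adding a
#'     tissue box filling the FOV;
#'   * `out_dir`: output directory (default `tempfile()`).
#' @param verbose log progress to stderr.
#' @return (invisibly) a list with `image` (`image_volume`), `kspaces`,
#'   `summary`, and the output paths.
#' @export
run_study <- function(config, verbose = TRUE) {
  t_start <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or YAML path")
  seed <- config$seed %||% 1L
  if (is.null(config$study) && is.null(config$phantom))
    stopf("config error: need either 'study' or an explicit 'phantom'")
  log_ <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  if (!is.null(config$study)) {
    preset <- make_study(config$study, scale = config$scale %||% 1,
                         phantom_name = config$phantom_name %||% "four_tube")
    phantom <- preset$phantom
    protocol <- preset$protocol
    n_traj <- config$n_trajectories %||% preset$n_trajectories
    ldens <- config$linear_density %||% preset$linear_density
    fluid <- preset$fluid
  } else {
    phantom <- config$phantom
    if (is.character(phantom)) {
      if (!file.exists(phantom))
        stopf("config error: phantom spec '%s' not found", phantom)
      phantom <- read_phantom_yaml(phantom)
    }
    if (!inherits(phantom, "phantom")) stopf("config error: invalid phantom")
    protocol <- config$protocol
    if (is.character(protocol)) {
      if (!file.exists(protocol))
        stopf("config error: protocol spec '%s' not found", protocol)
      protocol <- read_protocol_yaml(protocol)
    }
    if (!inherits(protocol, "tof_protocol")) stopf("config error: invalid protocol")
    n_traj <- config$n_trajectories %||% 256
    ldens <- config$linear_density %||% 3
    fluid <- make_bmf()
  }
  out_dir <- config$out_dir %||% tempfile("tofsim_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(config = config, protocol = unclass(protocol)))
  log_("run %s: tracing %d trajectories/channel", hash, n_traj)
  t0 <- Sys.time()
  components <- build_phantom_particles(phantom, fluid,
                                        n_trajectories = n_traj,
                                        linear_density = ldens,
                                        seed = seed)
  n_moving <- sum(vapply(components, function(p) length(p$label), numeric(1)))
  if (!is.null(config$stationary)) {
    sc <- config$stationary
    tis <- tissue_properties(T1 = sc$T1 %||% 1000, T2 = sc$T2 %||% 100,
                             rho = sc$rho %||% 0.7, name = "tissue")
    box <- list(lower = c(-protocol$FOV[1] / 2, -protocol$FOV[2] / 2,
                          -protocol$FOV[3] / 2),
                upper = c(protocol$FOV[1] / 2, protocol$FOV[2] / 2,
                          protocol$FOV[3] / 2))
    components <- c(components,
                    list(make_stationary_tissue(box, tis,
                                                density = sc$density %||% 1,
                                                exclude = phantom$channels,
                                                seed = seed + 1000L)))
  }
  t_seed <- Sys.time()
  plan <- plan_slabs(protocol$FOV[3], protocol$slab_width,
                     protocol$slab_overlap)
  slab_idx <- config$slabs %||% seq_len(nrow(plan))
  n_chunks <- config$n_chunks %||% 1L
  kspaces <- vector("list", length(slab_idx))
  images <- vector("list", length(slab_idx))
  for (j in seq_along(slab_idx)) {
    sl <- c(plan$z_min[slab_idx[j]], plan$z_max[slab_idx[j]])
    log_("slab %d/%d [%g, %g] mm", j, length(slab_idx), sl[1], sl[2])
    K <- NULL
    for (comp in components) {
      Kc <- if (!comp$stationary && n_chunks > 1L)
        run_chunked(comp, protocol, sl, n_chunks = n_chunks,
                    n_dummy = config$n_dummy %||% 0L)
      else simulate_slab(comp, protocol, sl, n_dummy = config$n_dummy %||% 0L)
      K <- if (is.null(K)) Kc else { K$data <- K$data + Kc$data; K }
    }
    if (!is.null(config$noise_sigma))
      K <- add_kspace_noise(K, config$noise_sigma, seed = seed + 2000L + j)
    if (!is.null(config$filter_alpha))
      K <- lowpass_filter(K, alpha = config$filter_alpha)
    kspaces[[j]] <- K
    images[[j]] <- reconstruct_magnitude(K, recon_matrix = config$recon_matrix)
  }
  t_acq <- Sys.time()
  image <- if (length(images) > 1L) {
    sub <- plan[slab_idx, , drop = FALSE]
    for (a in c("overlap", "slab_width")) attr(sub, a) <- attr(plan, a)
    composite_motsa(images, sub)
  } else images[[1L]]
  nii_path <- file.path(out_dir, "volume.nii.gz")
  write_image_nifti(image, nii_path)
  summary <- summarize(image, phantom = phantom, protocol = protocol,
                       plan = plan)
  summary$provenance <- list(config_hash = hash, seed = seed,
                             package_version = as.character(utils::packageVersion("tofsim")),
                             n_moving_particles = n_moving,
                             timing_s = list(
                               seeding = as.numeric(difftime(t_seed, t0, units = "secs")),
                               acquisition = as.numeric(difftime(t_acq, t_seed, units = "secs")),
                               total = as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_path <- file.path(out_dir, "run.log")
  writeLines(sprintf("tofsim run %s seed=%d particles=%d elapsed=%.1fs",
                     hash, seed, n_moving,
                     as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
             log_path)
  invisible(list(image = image, kspaces = kspaces, summary = summary,
                 paths = list(nifti = nii_path, summary = json_path,
                              log = log_path, dir = out_dir)))
}

#' Summarise a reconstructed volume
#'
#' Per-slice and per-slab intensity statistics: mean intensity per z slice,
#' entry-slice vs mid-slab lumen means for every slab, and the radial
#' intensity profile of straight channels (axis to wall).
#'
#' @param image an `image_volume`.
#' @param phantom optional [make_phantom()] (enables lumen statistics).
#' @param protocol the protocol used.
#' @param plan the slab plan (for entry/mid slice grouping).
#' @param n_bins radial profile bins.
#' @return a list of summary tables.
#' @export
summarize <- function(image, phantom = NULL, protocol = NULL, plan = NULL,
                      n_bins = 8) {
  d <- dim(image$data)
  out <- list(dim = d,
              slice_mean = apply(image$data, 3, mean),
              global_mean = mean(image$data))
  if (all(image$data == 0)) {
    out$note <- "empty image"
    return(out)
  }
  if (!is.null(phantom)) {
    mask <- lumen_mask(phantom, image)
    out$lumen_mean <- mean(image$data[mask])
    out$background_mean <- mean(image$data[!mask])
    zs <- voxel_coords(image, 3)
    lum_slice <- vapply(seq_len(d[3]), function(k) {
      m <- mask[, , k]
      if (any(m)) mean(image$data[, , k][m]) else NA_real_
    }, numeric(1))
    out$lumen_slice_mean <- lum_slice
    if (!is.null(plan)) {
      ## entry slices = first quarter of each slab in the flow (+z)
      ## direction; mid = central half
      entry <- numeric(0); mid <- numeric(0)
      for (i in seq_len(nrow(plan))) {
        inside <- which(zs >= plan$z_min[i] & zs <= plan$z_max[i])
        if (length(inside) < 4) next
        q <- length(inside) %/% 4
        entry <- c(entry, lum_slice[inside[seq_len(q)]])
        mid <- c(mid, lum_slice[inside[(q + 1):(3 * q)]])
      }
      out$entry_slice_lumen_mean <- mean(entry, na.rm = TRUE)
      out$mid_slab_lumen_mean <- mean(mid, na.rm = TRUE)
    }
    ## radial profile of the first straight channel, mid-volume slices
    straight <- which(vapply(phantom$channels,
                             function(ch) ch$geometry$kind == "straight",
                             logical(1)))
    prof_chan <- if (length(straight)) straight[1] else 1L
    out$radial_profile <- radial_profile(image, phantom, channel = prof_chan,
                                         n_bins = n_bins)
  }
  out
}

#' Radial intensity profile of a channel
#'
#' Mean image intensity in equal-width radius bins from the channel axis
#' to the wall, over the central third of the volume's slices.
#'
#' @param image an `image_volume`.
#' @param phantom the phantom.
#' @param channel channel index.
#' @param n_bins number of radius bins.
#' @return data.frame with `r_mid` (mm) and `intensity`.
#' @export
radial_profile <- function(image, phantom, channel = 1L, n_bins = 8) {
  ch <- phantom$channels[[channel]]
  R <- ch$geometry$diameter / 2
  xs <- voxel_coords(image, 1); ys <- voxel_coords(image, 2)
  zs <- voxel_coords(image, 3)
  d <- dim(image$data)
  kz <- which(zs > min(zs) + diff(range(zs)) / 3 &
              zs < max(zs) - diff(range(zs)) / 3)
  if (length(kz) == 0) kz <- seq_len(d[3])
  rx <- outer(xs - ch$center[1], ys - ch$center[2],
              function(a, b) sqrt(a^2 + b^2))
  breaks <- seq(0, R, length.out = n_bins + 1)
  bin <- cut(rx, breaks, include.lowest = TRUE, labels = FALSE)
  vals <- vapply(seq_len(n_bins), function(b) {
    sel <- which(bin == b)
    if (length(sel) == 0) return(NA_real_)
    mean(vapply(kz, function(k) mean(image$data[, , k][sel]), numeric(1)))
  }, numeric(1))
  data.frame(r_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             intensity = vals)
}
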