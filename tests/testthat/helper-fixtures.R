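# Shared fixtures: tiny protocols / phantoms built in code.

tiny_protocol <- function(Nx = 32, Ny = 16, Nz = 8, FOVxy = 32,
                          slab_width = 16, TE = 4.7, TR = 40, FA = 20,
                          readout_window = 3.2, ...) {
  tof_protocol(TE = TE, TR = TR, FA = FA,
               matrix = c(Nx, Ny, Nz),
               FOV = c(FOVxy, FOVxy, slab_width),
               slab_width = slab_width,
               readout_window = readout_window, ...)
}

## a stationary particle_set from explicit positions
stationary_set <- function(pos, tissue = tissue_properties(850, 170, 1),
                           volume = 1) {
  n <- nrow(pos)
  ps <- list(label = seq_len(n), traj = rep(0L, n),
             tshift = rep(NA_real_, n),
             volume = rep_len(volume, n), tissue_id = rep(1L, n),
             M = cbind(numeric(n), numeric(n), rep(tissue$rho, n)),
             pos0 = pos, tissues = list(tissue), bundle = NULL,
             seedings = NULL, t0 = 0, next_birth = numeric(0),
             n_label = n, stationary = TRUE)
  class(ps) <- "particle_set"
  ps
}

## uniform random points in a disc of radius R (fixed seed)
disc_points <- function(n, R, seed = 1, z = c(-8, 8)) {
  set.seed(seed)
  r <- sqrt(runif(n)) * R
  th <- runif(n) * 2 * pi
  cbind(r * cos(th), r * sin(th), runif(n, z[1], z[2]))
}

## small flowing particle set in a straight or stenosed tube
tiny_flow_set <- function(kind = "straight", n_traj = 8, d = 8, L = 60,
                          Q = 2.5, linear_density = 3, f = 0.5,
                          step_length = 0.5) {
  geom <- if (kind == "straight") make_geometry("straight", d, L)
          else make_geometry("stenosed", d, L, stenosis_fraction = f)
  field <- flow_field(geom, Q)
  ip <- sunflower_points(n_traj, d / 2 * 0.95)
  bundle <- trace_trajectories(field, ip, step_length = step_length)
  sd <- seed_trajectories(bundle, linear_density, inlet_radius = d / 2)
  ps <- populate(sd, bundle, make_bmf())
  attr(ps, "transform") <- list(origin = c(0, 0, -L / 2), zsign = 1)
  attr(ps, "flow_sign") <- 1
  ps
}
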