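# tofsim — particle-tracing simulation of Time-of-Flight MR angiography

`tofsim` synthesises 3D Time-of-Flight (ToF) MR angiograms of digital
vascular phantoms, for people who need controlled, ground-truth MRA data:
developers of vessel segmentation or enhancement algorithms, sequence
designers exploring slab/ramp/presaturation trade-offs, and anyone who
wants to see how inflow contrast emerges from spin physics.

Blood is modelled as a cloud of volume-weighted spin packets advected
along laminar flow trajectories (a Lagrangian model — no fluid is ever
transported across a voxel grid, so there is no numerical diffusion).
Each particle's magnetization **M** evolves by the closed-form
discrete-time Bloch operators

- relaxation: `Mxy -> Mxy exp(-dt/T2)`, `Mz -> M0 + (Mz - M0) exp(-dt/T1)`,
- precession: rotation of `Mxy` about z by (offset x dt),
- excitation: rotation by `alpha_eff = tau * sqrt(omega1^2 + domega^2)`
  about the effective-field axis tilted `theta = atan2(omega1, domega)`
  from B0,

driving a spoiled gradient-echo (SPGR) ToF sequence with MOTSA (multiple
overlapping thin slabs), TONE (linearly ramped flip angle along the
flow), spatial presaturation and first-moment flow compensation. One
k-space line is filled per TR from the volume-weighted signal
`S = sum_i V_i (Mx_i + i My_i)`; between samples the clock advances by
`readout_window / Nx`, particle positions are re-interpolated on the flow
grid, and out-flowed particles are replaced by fresh, unsaturated spins —
the mechanism behind inflow enhancement. Magnitude images come from a
centred inverse FFT with optional Tukey filtering, zero padding, MOTSA
compositing and Gaussian k-space noise.

The stationary-tissue steady state follows the Ernst formula
`M0 sin(a) (1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR/T1)`, while fully
refreshed inflowing spins give `M0 sin(a)`; the package reproduces both
to 0.1%, and that ratio is the ToF contrast everything else modulates.

A validation toolkit mirrors a quantitative comparison workflow: 3D
non-local-means denoising, integer-shift alignment, Pearson correlation
with Fisher-z 95% intervals, and RMSE after common intensity scaling.

## Worked example

A 50%-stenosed 8-mm tube carrying 2.5 ml/s, imaged with a reduced-scale
protocol (TE/TR/FA = 4.7/40/20°, one 16-mm slab, 32x32x8 matrix, TONE):

```r
library(tofsim)

phantom  <- make_phantom("stenosis50", flow_rate = 2.5)
protocol <- tof_protocol(TE = 4.7, TR = 40, FA = 20,
                         matrix = c(32, 32, 8), FOV = c(24, 24, 16),
                         slab_width = 16, readout_window = 3.2,
                         TONE = list(enabled = TRUE, span = 20))

particles <- build_phantom_particles(phantom, n_trajectories = 24,
                                     linear_density = 3)[[1]]
K     <- simulate_slab(particles, protocol)
image <- reconstruct_magnitude(K)

mask <- lumen_mask(phantom, image)
cat(sprintf("lumen mean %.3f vs background mean %.3f\n",
            mean(image$data[mask]), mean(image$data[!mask])))

Kn    <- add_kspace_noise(K, sigma = 0.02 * max(Mod(K$data)), seed = 7)
noisy <- reconstruct_magnitude(Kn)
den   <- nlm_denoise_3d(noisy$data, patch_radius = 1, search_radius = 3)
compare_vois(den, image$data)
```

which prints (about 20 s on one core):

```
lumen mean 0.435 vs background mean 0.023
Correlation coefficient  Lower bound  Upper bound  RMS error
                0.9360       0.9333       0.9387     0.0309   (n = 8192, 95% CI)
```

The lumen is ~19x brighter than the unexcited surround (inflow
enhancement with no stationary tissue in the box); denoising the noisy
replicate recovers a 0.94 correlation against the noise-free volume.

Full experiment presets reproducing the validation phantom set — straight
207-mm channels of 8/5 mm, 75% and 50% stenoses, a 44-mm-radius U-bend,
blood-mimicking fluid (T1/T2 = 850/170 ms) at 2.5–10 ml/s — are bundled:

```r
preset <- make_study(1, scale = 0.15)   # 2.5 ml/s, 4.7/40/20 deg, 44/8 slabs
res <- run_study(list(study = 1, scale = 0.15, seed = 1,
                      out_dir = "study1"))
```

(`scale` multiplies the acquisition matrix and the trajectory count;
physics parameters are untouched. Scale 0.15 — a 34x24 matrix over four
44-mm slabs with 38 trajectories per tube — runs in minutes on one core;
scale 1 is the full 224x160x44, 256-trajectory acquisition.)

`run_study` writes a NIfTI volume, a JSON summary (per-slice and lumen
statistics, radial profiles, config hash, seed, timings) and a log. A
thin command-line front end lives at `inst/cli/tofsim.R`
(`tofsim.R run --study 1 --scale 0.25 --seed 1 --out study1`).

The methods vignette (`vignettes/tof-simulation-methods.Rmd`) documents
the flow model, the Voronoi volume weighting, the Bloch kernel and its
conventions, every tunable parameter with units and defaults, and what
the synthetic phantoms do and do not establish about real acquisitions.

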