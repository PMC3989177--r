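---
title: "Particle-tracing simulation of Time-of-Flight MR angiography: models and methods"
author: "tofsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-tracing simulation of Time-of-Flight MR angiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`tofsim` synthesises 3D Time-of-Flight (ToF) MR angiograms of digital
vascular phantoms. The pipeline is Lagrangian throughout: blood is a cloud
of spin-carrying particles advected along flow trajectories, and every
image-formation step (excitation, encoding, sampling) acts on particles at
their instantaneous positions. Tracking fluid portions instead of
transporting magnetization across a fixed voxel lattice avoids numerical
diffusion — the progressive smearing of a fluid portion over neighbouring
mesh cells that a Eulerian update suffers at every time step, and which
would misplace spins precisely where ToF contrast is made (vessel inflow
zones).

The stages are:

1. **Flow phantom** — parametric vessel geometries (straight tube,
   cosine-tapered stenosis, U-bend) carrying an analytic laminar Poiseuille
   field; particle trajectories integrated through it.
2. **Particle seeding** — Voronoi tessellation of the inlet disc assigns
   each trajectory a cross-sectional area; particles placed along
   trajectories carry the prism volume `A_i * dl_i`, constant for the
   whole trajectory; fresh particles are injected at the inlet at the rate
   the flow removes them at the outlet.
3. **Bloch kernel** — closed-form discrete-time evolution (rotations +
   exponential relaxation) of each particle's magnetization vector.
4. **ToF sequence** — spoiled gradient echo (SPGR) with multiple
   overlapping thin slabs (MOTSA), linearly ramped excitation (TONE),
   spatial presaturation and first-moment flow compensation.
5. **Acquisition engine** — one k-space line per TR; between samples the
   clock advances by `readout_window / Nx`, positions are re-interpolated,
   relaxation applied, outflowed particles retired and fresh ones injected.
6. **Reconstruction** — optional Tukey low-pass filtering and zero
   padding, centred inverse FFT, magnitude; MOTSA slabs composited.
7. **Validation toolkit** — 3D non-local-means denoising, integer-shift
   alignment, Pearson correlation with Fisher-z confidence intervals,
   min–max-scaled RMSE, SNR estimation.

Units everywhere: mm, ms, mT/m, rad; flow rates in mm^3/ms, numerically
identical to ml/s.

# Flow model

The package replaces a CFD stage with an analytic laminar field. At arc
length $s$ along the centerline the lumen radius is $R(s)$ and the axial
speed at fractional radius $\tilde r = r/R(s)$ is

$$ v(s, \tilde r) = v_{max}(s)\,(1 - \tilde r^2), \qquad
   v_{max}(s) = \frac{2Q}{\pi R(s)^2}, $$

which enforces no slip at the wall and a volumetric flux of exactly $Q$
through every cross-section (continuity). Streamlines keep their
fractional radius — the quasi-1D approximation for slowly varying lumens.
Consequences worth stating plainly:

* acceleration through a stenosis — a particle's speed time-course is
  flat, rises sharply through the throat and relaxes after it — is
  reproduced exactly (mean speed scales with the inverse area ratio:
  a 50% diameter stenosis quadruples it);
* the asymmetric post-stenotic jet and any turbulent or chaotic behaviour
  of a real narrowing are **not** modelled; the simulated post-throat
  lumen is axisymmetric.

A 75% diameter stenosis leaves a 2-mm throat; "% of diameter" is read as
throat diameter $= (1-f)\,d$. The neck is a $C^1$ cosine taper over 10 mm
(the shape of the physical phantom neck is not published; any smooth neck
of the same throat behaves equivalently at the imaging resolution).

Trajectories integrate $\mathrm{d}s/\mathrm{d}t = v(s,\tilde r)$ with the
explicit midpoint rule (RK2). The tracer chooses the per-trajectory step
so that one step covers about 0.25–0.5 mm of path at the inlet speed:
slow near-wall threads then use proportionally longer time steps and every
trajectory resolves the geometry equally well. Positions at arbitrary
times are linear interpolations between flow samples; the flow clock
(`dt_flow`) and the MR sampling clock are independent grids by design.

# Seeding and volume weighting

The inlet disc is tessellated by the Voronoi cells of the trajectory seed
points (sunflower layout by default: even coverage without the clustering
of uniform random seeds). Cell areas are computed exactly — bisector
half-plane clipping followed by closed-form convex-polygon/disc
intersection — so the areas sum to $\pi R^2$ at machine precision and the
total particle volume closes on the lumen volume to well under 1%.

Particle $k$ of trajectory $i$ sits where the fluid thread was at time
$k\,\Delta t_i$ after entering, with $\Delta t_i = \Delta l_i / v_i(0)$
and $\Delta l_i = 1/3$ mm by default (3 particles per millimetre of vessel
length, 256 trajectories per tube). In a narrowing the spacing stretches
exactly as the Voronoi-scaled area shrinks, so the per-particle volume
$V_i = A_i \Delta l_i$ is constant along the trajectory and no 3D
tessellation is ever needed. $V_i$ weights the particle's contribution to
the MR signal.

With this seeding the four-tube phantom (three 8-mm tubes, one 5-mm tube,
207 mm long) averages about 21 particles/mm^3 over the tubes — the narrow
tube is denser because the same 256 trajectories share a quarter of the
area — and about 12 particles per 0.65-mm^3 acquisition voxel pooled over
the phantom.

Stationary tissue is a uniform random cloud in a user box, lumens carved
out, each particle carrying `1/density` mm^3. Every tissue component is
simulated separately and the k-spaces summed; the signal is strictly
linear in the particles, so this is exact, and it is also what makes
trajectory chunking (the in-process counterpart of the original
master/agent grid reduction) bit-stable: chunk k-spaces are summed in
chunk order, and a chunked run equals the single-chunk run to float
round-off.

# Spin physics

Between events the analytic Bloch solution applies operators to each
particle's $(M_x, M_y, M_z)$:

* **Relaxation** over $\Delta t$: transverse scaled by $e^{-\Delta t/T_2}$,
  longitudinal pulled to equilibrium, $M_z \to M_0 + (M_z - M_0)e^{-\Delta t/T_1}$.
  The recovery term is essential: without it there is neither a spoiled
  steady state nor inflow contrast.
* **Precession**: rotation of the transverse plane about $z$ by
  (offset $\times\,\Delta t$) — used for phase encodes, readout phase and
  off-resonance.
* **Excitation**: a rectangular pulse of nominal flip $\alpha$ and
  duration $\tau$ has on-resonance rate $\omega_1 = \alpha/\tau$; with
  off-resonance $\Delta\omega$ the rotation is by
  $\alpha_{eff} = \tau\sqrt{\omega_1^2 + \Delta\omega^2}$ about an axis
  tilted $\theta = \operatorname{atan2}(\omega_1, \Delta\omega)$ from $+z$.
  The pulse is divided into substeps (8 for moving spins, 1 for
  stationary — sub-rotations about a fixed axis commute, so stationary
  spins need no subdivision); positions refresh each substep, so a spin
  that leaves the slab mid-pulse is only partially tipped.
* **Spoiling**: ideal — transverse magnetization zeroed at the end of
  every TR.

Convention: RF phase 0 puts the effective field along $+x$ and a positive
flip takes $+z$ to $-y$. Only relative phases matter for magnitude
images; the choice is stated so raw k-space dumps are interpretable (one
visible consequence: the on-resonance k-space satisfies
$S(-k) = -\overline{S(k)}$ rather than the textbook Hermitian identity,
the $-1$ being the square of the global receiver phase $-i$).

Two closed forms anchor the kernel: the spoiled steady state (Ernst)
$M_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$ for stationary spins, and the
inflow limit $M_0\sin\alpha$ for fully refreshed spins — their ratio is
the ideal ToF contrast. Both are reproduced by operator iteration to
better than 0.1%.

# Sequence and acquisition

Each TR runs: optional presaturation (ideal 90° + spoil of every spin in
a 40-mm band, 5 mm beyond the slab on the configured side, once per TR) →
RF (TONE-ramped: nominal flip at slab centre, total span 20° edge to
edge, rising in the flow direction; the published description leaves open
whether the vendor ramp is strictly linear — linear is implemented) →
instantaneous phase-encode and readout-prephase rotations → relaxation to
the first sample → `Nx` samples at `dt = readout_window/Nx` with
re-interpolation, per-step readout precession
($-2\pi\,x/\mathrm{FOV}_x$ per k-step) and relaxation → relaxation to TR →
spoiler. Line ordering is sequential `ky` within ascending `kz`; ordering
only shapes transient-state artifacts.

Flow compensation has two faces here. The waveform designer
(`flow_comp_waveform`) solves a bipolar prephaser whose zeroth moment
matches the base lobe while the first moment of prephaser + readout
vanishes at the echo, verified by numerical integration of
$\gamma\int G(t)x(t)\mathrm{d}t$ for moving spins. Inside the acquisition
loop the same physics is applied in its exact limit: on compensated axes
the encode rotation reads the particle position at the echo centre
(perfect first-moment nulling for constant velocity) instead of at the
encode instant. Gradient ramp shapes are otherwise not modelled — the
analytic Bloch solution is only valid for piecewise-constant fields, and
it is the moments, not the lobe shapes, that the spin phase sees.

Dark-entry physics falls out of bookkeeping rather than special cases:
spins that cross the outlet are retired at the sample step where they
cross; replacements enter with no transverse magnetization and stay
silent until the next excitation, which is what darkens voxels where
fast blood enters mid-readout.

Two implementation notes with no physical consequence:

* After the spoiler only spins excited in the current TR can carry
  transverse magnetization, so the per-sample loop runs over the "hot"
  subset (spins within one TR's travel of the slab, plus any born before
  the pulse ends); everything else receives one longitudinal-relaxation
  update per TR. Exponential relaxation composes exactly, so this is
  identical to the naive loop (the test suite checks the engine against a
  per-particle brute-force evolution to 1e-9).
* Relaxation during the RF pulse itself (0.6 ms against T1/T2 of
  hundreds of ms) is neglected, uniformly for all spins.

# Reconstruction

K-space is stored centred (DC at index `floor(N/2)+1`). Reconstruction is
`magnitude(fftshift(IFFT(ifftshift(K))))`; voxel `j` (0-based) sits at
`(j - N/2) * FOV/N`. Zero padding embeds the measured grid centrally
(sinc interpolation; the in-plane default target is 256, matching the
padded matrices of the reference acquisitions). The optional phase-encode
low-pass is a separable Tukey window with unit DC gain (taper 0.5 by
default; the reference pipeline used an unspecified Matlab filter, so the
window family and taper are free choices here). MOTSA slabs composite by
discarding half the overlap from each adjoining slab (boundary slices
come from exactly one slab) or by voxelwise maximum. Optional complex
Gaussian noise added to k-space yields the expected Rayleigh background
(mean $\sigma\sqrt{\pi/2}$ under the unitary normalisation).

# Validation toolkit

The non-local means filter follows the weighted-mean-of-other-voxels
definition with patch distances that exclude the centre voxel,
`w = exp(-d^2/h^2)`; the practical filter restricts candidates to a
search window (radius 5 by default, patch radius 1) and a full-image mode
exists for tiny volumes so a brute-force double loop can check it
exactly. Borders are edge-replicated — a convention shared by the test
oracle; border voxels therefore see a few clamped duplicate candidates,
interior voxels the ideal set. Where every candidate weight underflows to
zero in double precision (isolated voxels at very strong edges with small
`h`), the voxel keeps its original value — the standard practical-NLM
fallback when no admissible average exists. `h` defaults to a pseudo-residual estimate
of the noise sd (MAD of neighbour half-differences). Denoising assumes
Gaussian noise, a good approximation of Rician magnitude noise above
SNR ≈ 3; `estimate_snr` warns below that.

Volume comparison: integer-voxel translation search maximising normalised
cross-correlation (the reference workflow registered real scanner images
by mutual information; synthetic/synthetic comparisons share a frame, so
sub-voxel 6-DOF registration is out of scope), then Pearson r with the
Fisher-z 95% interval and RMSE after min–max scaling both volumes to
[0, 1]. VOI selection is caller-supplied.

# Synthetic data: what it does and does not establish

The bundled phantoms reproduce the geometry of a physical flow-calibration
set: straight 207-mm channels of 8 and 5 mm, 75% and 50% diameter
stenoses, a U-bend of 44-mm curvature radius, driven by a
glycerol/water blood-mimicking fluid (T1 = 850 ms, T2 = 170 ms, relative
proton density 1.00 at 1.5 T) at 2.5–10 ml/s, with the four bundled
protocol presets (TE/TR/FA of 4.7/40/20°, 4.7/40/15°, 4.6/27/15° at
44/8-mm slabs and 4.6/27/15° at 25/5-mm slabs; 224×160 in-plane sampling,
1-mm slices, 1.5 T).

Passing tests on these phantoms show that the sequence physics —
inflow enhancement, slab-entry voids, parabolic lumen shading,
presaturation of counter-flow, moment-nulled readout phase — emerges from
the particle model under controlled laminar flow. They do not show
fidelity to real acquisitions of turbulent post-stenotic flow, pulsatile
waveforms, organ motion, magnetization transfer or coil/noise behaviour:
none of these are modelled.

# Problem sizes and numerical choices

The test suite and the acceptance script run reduced-scale acquisitions —
64×64×16 and 64×64×8 matrices over a 44- or 16-mm slab with 14–24
trajectories per tube — chosen as the smallest grids on which the
sequence features are unambiguous; full-scale presets
(224×160×44, 256 trajectories) run through exactly the same code path via
`make_study(n, scale = 1)`. Other fixed choices: readout window defaults
to 6 ms at full scale (3.2 ms in the reduced protocols), rectangular RF of
0.6 ms, RK2 tracer step ≈ 0.25–0.5 mm of path, seeding determinism under a
caller seed, and tie-breaks at slab edges resolved by closed intervals
(`z` exactly on an edge is inside; tests avoid placing particles on the
lattice of measure-zero boundaries).

# Known limitations

Laminar, steady, Newtonian flow only; axisymmetric stenoses; ideal
rectangular slab profiles and ideal spoiling; no magnetization transfer;
no eddy currents or coil sensitivities; translation-only alignment; the
per-axis flow-compensation switches model moment nulling, not any
vendor's actual lobe trains.
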