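---
title: "Two-stage 3D cone trajectory design and dynamic reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage 3D cone trajectory design and dynamic reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(conetraj)
```

## The problem

Simultaneous time-resolved angiography and perfusion imaging with arterial
spin labeling (ASL) acquires one continuous non-Cartesian readout train
after each labeling preparation and reconstructs it twice: a high
spatio-temporal-resolution angiographic series from the full k-space extent
of a short temporal window, and a low-resolution perfusion series from the
central k-space region of a broader window. A 3D golden-ratio *radial*
readout supports this dual binning naturally but samples the k-space
periphery poorly. `conetraj` implements the alternative this package is
built around: each radial spoke is replaced by a center-out *cone* that
sweeps far more k-space per excitation while keeping the golden-ratio
temporal flexibility.

## The two-stage cone model

A single shot is the curve, for curve parameter $\alpha \in (0, 1]$ and
cone axis $\hat k_z$:

$$
\vec k(\alpha) =
\begin{cases}
\hat k_z k_\max \cos\theta\,\alpha +
(\hat k_x \cos A\alpha + \hat k_y \sin A\alpha)\, m^{\,n-1} k_\max
\sin\theta\,\alpha, & 0 < \alpha \le m,\\[4pt]
\hat k_z k_\max \cos\theta\,\alpha +
(\hat k_x \cos A\alpha + \hat k_y \sin A\alpha)\, k_\max
\sin\theta\,\alpha^{\,n}, & m < \alpha \le 1.
\end{cases}
$$

* $\theta$ (degrees) — the half-angle between the trajectory endpoint and
  the axis. Large $\theta$ buys peripheral coverage per shot.
* $m \in [0,1]$ — the stage separation point. Stage 1 ($\alpha \le m$) is a
  conventional fixed-angle cone of half-angle
  $\arctan(m^{n-1}\tan\theta)$; stage 2 lets the cone angle grow with
  radius. $m = 0$ collapses the design to the single-stage $\alpha^n$ law.
* $n \ge 1$ — the curvature power of stage 2.
* $A$ (radians) — the total azimuthal twist. It is not chosen directly:
  [solve_twist_scaling()] finds the $A$ whose *time-optimal* traversal
  under the gradient limits matches the requested readout duration,
  exploiting that traversal time is non-decreasing in $A$.

The $m^{n-1}$ factor in stage 1 is the unique choice that makes the two
branches agree exactly at $\alpha = m$; the suite asserts this continuity
to $10^{-12}$ on a thousand random parameter draws. Angles are degrees at
every interface and radians internally.

## Gradient waveform synthesis

[time_optimal_waveform()] re-parameterizes the curve by arc length and
runs the standard forward–backward speed-profile integration: speed is
capped by the amplitude limit $\gamma G_\max$ and the centripetal
constraint $v^2\kappa \le \gamma S_\max$, and tangential acceleration by
the slew budget left after the centripetal component. Zero speed is
imposed at both ends, so the gradients ramp up from and return to zero;
for a straight line with generous amplitude headroom this reproduces the
triangular-ramp closed form $T = 2\sqrt{\kappa_{\mathrm{ext}}/(\gamma
S_\max)}$, which the suite checks to 1%.

Numerical choices that matter:

* The raster-sampled gradient is obtained by *sampling the continuous
  profile* $g(t) = v(t)\,T(s(t))/\gamma$ at interval midpoints rather than
  by finite-differencing interpolated k-space positions; exactly sampled
  gradients inherit the continuous amplitude and slew bounds, which
  finite differences do not.
* Both limits are derated by 1% during the search and the final waveform
  is verified against the *stated* limits; if discretization error still
  produces an overshoot, the whole profile is slowed by the smallest
  factor that removes it (at most a few tenths of a percent). The
  returned waveform therefore always satisfies the hardware limits
  exactly — that is the hard constraint; the 1% duration optimality claim
  is the soft one.
* The two-stage junction at $\alpha = m$ has a tangent kink (the radial
  growth rate jumps by the factor $n$), so the traversal time depends
  mildly on how finely the geometry is discretized there. The package
  uses one density rule everywhere — at least 2000 $\alpha$ samples and
  250 per radian of twist — so the twist solved for a target duration and
  the final re-timed waveform are mutually consistent.
* $\gamma$ defaults to 42.5764 kHz/mT (proton); raster 10 µs and ADC
  dwell 2 µs are typical scanner values, all configurable.

## Shot ordering and binning

Shot axes follow the two-golden-mean sphere sequence: for shot index $i$,
$z = 2\,\mathrm{frac}(i\phi_1) - 1$ and azimuth $2\pi\,\mathrm{frac}
(i\phi_2)$ with $\phi_1 = 0.46561\ldots$, $\phi_2 = 0.68233\ldots$ — the
axes cover the *full* sphere, because each cone only covers a cap around
its axis. Any contiguous index run covers the sphere near-uniformly
(checked against uniform-random axes with a Monte-Carlo spherical-cap
discrepancy oracle). The shot at repeat $r$ and readout (TR) index $t$
receives index $i = t\,n_{\mathrm{rep}} + r$: the rotation increments
first across repeats, then across time, so binning all repeats of any
contiguous TR window always yields a contiguous golden-ratio set. Each
cone is additionally spun about its own axis by a seeded uniform random
angle in $[0, 2\pi)$ — the distribution is our choice, as only "random"
is specified — which decorrelates the twist phase of overlapping cones.
[bin_frames()] then groups shots into frames by TR start time and applies
the central-radius cut; because rotations preserve $|k|$, one per-sample
radial mask serves every shot. The angiographic convention of using half
the shots of a window is implemented as the *first half of the repeats*,
which keeps golden-index contiguity — the property the ordering is
designed to provide.

## Metrics

* **Density compensation** is the iterative gridding-density scheme
  (Pipe–Menon style), fixed at 20 iterations with the per-iteration
  change logged; the method is not dictated by the underlying design, so
  a trajectory-agnostic choice was preferred. On dense radial sets the
  weights follow the analytic $r^2$ law in the interior; the outermost
  shell is a truncation boundary and is excluded from that check.
* **PSF / FWHM**: density-compensated adjoint NUFFT of all-ones data,
  peak-normalized; widths per cardinal axis from 8× Fourier-zero-padded
  profiles with linear interpolation of the half-maximum crossings
  (deterministic sub-voxel precision). A Gaussian of known $\sigma$ is
  recovered within 1% of $2.3548\sigma$.
* **Effective SNR** uses pseudo-replicas: many reconstructions with fresh
  complex Gaussian noise; the per-voxel replica standard deviation
  *averaged over the foreground* is the noise (the foreground-averaged
  reading was chosen over a global average, as the foreground is where
  the signal claim lives), and the plain SNR is divided by the product of
  the three axis FWHMs in voxels as a voxel-volume proxy. 64 replicas by
  default; the noise level is specified relative to the peak (DC) data
  magnitude so that it transfers across phantoms.
* **SAPR** is mean foreground power over mean background power, exactly
  as defined; zero background power returns a flagged infinity.

## Phantoms and forward model

The synthetic phantoms stand in for measured references: a sparse
tube phantom (spline centerlines, 1–2.5 voxel tapering radii, < 5%
foreground) for the angiographic volume, a smooth nested-ellipsoid
compartment phantom for perfusion — low-pass filtered so less than 1% of
its spectral energy lies above half the grid Nyquist, keeping a
central-third reconstruction meaningful — and a bar-pattern comb for
resolution scoring. Coil sensitivities are smooth complex Gaussian
profiles for 8 coils on a ring (8 matching a typical post-compression
channel count). The forward model is a plain sensitivity-weighted NUFFT
plus optional i.i.d. complex Gaussian noise; it contains no relaxation or
off-resonance physics, no ASL signal model, and no motion — so passing
tests demonstrate sampling/reconstruction behavior, not robustness to
those real-world effects. All generators are pure functions of their
parameters and seed.

## Reconstruction

[adjoint_recon()] is the density-compensated adjoint with
conjugate-sensitivity coil combination. [llr_recon()] minimizes

$$\sum_f \|PFCx_f - y_f\|^2 + \lambda \sum_i \|R_i x\|_*$$

by FISTA-style accelerated proximal gradient with a monotone safeguard:
the proximal map is singular-value soft-thresholding of every
non-overlapping space×time patch matrix (default 5×5×5 voxels ×
frames); if an accelerated step would raise the objective, the step is
retaken without momentum and backtracked. $\lambda$ (default $10^{-1}$)
is interpreted on data normalized so the unweighted adjoint image has
unit peak magnitude, making the value transferable across scales. The
patch tiling offset is drawn once per solve from the seed; redrawing it
every iteration (cycle spinning, `cycle_spin = TRUE`) suppresses blocking
at patch boundaries but makes the recorded objective only approximately
monotone because the regularizer's tiling changes between iterations —
the fixed-tiling default keeps the objective a single well-defined,
provably non-increasing function. Stopping: 200 iterations or relative
objective change below $10^{-6}$. At $\lambda = 0$ the solver agrees with
an independent conjugate-gradient least-squares oracle to $10^{-3}$
relative RMS. The radial Hann window $w(|k|) = \tfrac12(1 +
\cos(\pi|k|/k_\max))$ can be applied in both the adjoint and iterative
paths (one protocol-wide apodization statement covers both, so both are
toggleable).

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is cleanly measurable: NUFFT
and adjoint checks at 12–16³ against a direct DFT; metric suites at
24–64³; the least-squares comparison at 32³ with 4 frames and 2 coils;
the PSF-ordering regression at 64³ with the full 48-repeat, 288-shot
angiographic frame at 8 µs dwell. The protocol arithmetic is exact at any
scale.

## Known limitations

* The qualitative ordering "two-stage ($m = 0.5$) PSF no wider than
  single-stage ($m = 0$) under angiographic binning" is recorded as a
  regression check. At the desk-scale conditions above our pipeline
  measures the *opposite* ordering by a consistent 0.2–1.2% margin across
  matrix sizes 64–128, dwell 4–8 µs, 8–48 repeats, and with or without
  Hann apodization, while all quantitative guarantees (continuity,
  feasibility, protocol arithmetic, solver correctness) hold. The
  ordering evidently depends on conditions we do not reproduce (full
  in-vivo FOV/matrix, the exact density-compensation scheme, measured
  rather than simulated data), so the check documents the present
  behavior rather than confirming the expected ordering.
* No eddy-current / gradient-impulse-response modeling: the designed and
  realized trajectories are assumed identical.
* No ASL physics: label/control is a boolean tag, flip-angle schedules
  are carried as data, and the dynamic phantom's inflow/perfusion
  profiles are phenomenological.
* Trajectory and schedule exports are CSV (with NIfTI for volumes and
  YAML for configurations); all formats round-trip losslessly through the
  matching readers.

## A worked design

```{r design}
limits <- hardware_limits(g_max = 11.64, s_max = 61.54)
params <- cone_params(theta = 60, m = 0.5, n = 3,
                      k_max = kmax_for_resolution(1.13),
                      readout_duration = 10)
design <- design_cone(params, limits)
waveform_peaks(design$waveform)

protocol <- protocol_params(tr = 14.7, train_duration = 2116.8)
schedule <- build_schedule(protocol, n_repeats = 48, seed = 1)
adc <- resample_adc(design$waveform, dwell = 2)
binning <- bin_frames(schedule, adc$k, temporal_window = 176.4,
                      half_shots = TRUE)
binning$n_frames
```
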