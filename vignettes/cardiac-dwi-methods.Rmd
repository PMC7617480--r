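---
title: "Methods: waveform design and the cardiac DWI analysis chain"
author: "cdwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform design and the cardiac DWI analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cdwi)
```

`cdwi` implements the computational chain of spin-echo cardiac
diffusion-weighted MRI on a high-performance (300 mT/m) gradient system:
the numerical design of motion-compensated, Maxwell-compensated diffusion
encoding waveforms; a synthetic left-ventricle (LV) data generator with
known ground truth; and the analysis pipeline from complex-valued images
to myocardial microstructure maps and scheme comparisons. This vignette
explains the models, the conventions, the tunable parameters, and the
limits of what the synthetic tests demonstrate.

## 1. Gradient waveform design

### Model

A spin-echo diffusion preparation has two encoding slots separated by the
refocusing pulse (`sequence_timing`). The refocusing pulse negates the
accumulated spin phase, which we represent with the effective sign
function $s(t)$ (+1 before, −1 after the pulse, 0 during it). For a
single-axis ("linear b-tensor") waveform $G(t)$ the relevant quantities
are

- **b-value** $b = \int q(t)^2\,dt$, with
  $q(t) = \gamma \int_0^t s(\tau) G(\tau)\, d\tau$;
- **moments** $m_k = \gamma \int s(t)\,G(t)\,t^k\,dt$ — nulling
  $m_0 \dots m_n$ removes sensitivity to bulk displacement, velocity
  ($n\ge1$), acceleration ($n\ge2$) and jerk ($n\ge3$). We call a design
  with $m_0..m_2$ nulled **M2**, with $m_0..m_3$ nulled **M3**;
- **Maxwell (concomitant-field) index**
  $\left\lVert \int s(t)\, \mathbf{g}(t) \mathbf{g}(t)^{\mathsf T} dt \right\rVert_F$
  with $\mathbf g = G(t)\,\hat d$. Asymmetric waveforms played at high
  amplitude otherwise accrue a concomitant phase that scales with $G^2$
  and corrupts the signal; driving this index to zero is the standard
  compensation.

### Optimization

`optimize_waveform()` discretizes the encoding time into `n_timesteps`
(default 77) equal steps and maximizes the b-value (a positive
semidefinite quadratic form in the amplitudes) subject to: amplitude
$|G| \le 300$ mT/m, slew $\le 80$ T/m/s (forward differences, applied per
grid interval — a deliberately conservative limit relative to hardware,
reflecting nerve-stimulation safety), moments $|m_k| \le 10^{-4}$
s$^k$/m, and the Maxwell equality. Numerically:

1. the moment constraints (linear) are eliminated exactly by a null-space
   parametrization, so every iterate is moment-nulled to machine
   precision;
2. amplitude/slew violations are penalized and the Maxwell residual is
   handled by an augmented-Lagrangian term, minimized with L-BFGS-B;
3. a repair step follows: an exact scalar-Newton correction of the
   (quadratic) Maxwell residual inside the moment null space, then a
   global down-scaling into the amplitude/slew box. Down-scaling
   preserves moment nulling (zero scales to zero) and shrinks the
   Maxwell residual quadratically, so the returned waveform satisfies
   all constraints simultaneously.

The problem is nonconvex (a convex quadratic is maximized), so the solver
restarts from `n_restarts` (default 10) smoothed uniform-random waveforms
and keeps the best; runs are bit-reproducible given the seed. The
monotone costs — higher motion order never gains b, enabling Maxwell
compensation never gains b — are enforced by nested feasible sets and
verified in the tests.

### Timing, scaling, rasterization

The slot durations are inputs. `protocol_timing()` provides the defaults
used throughout: 32/4/16 ms and 35/4/19 ms (pre-180 / refocusing /
post-180) for M2 and M3. These are the package's own choice of slot
splits consistent with echo times of 74 and 80 ms once excitation and an
EPI readout-to-echo time of about 21 ms are accounted for; they admit
maximum b-values of roughly 1840 (M2) and 1700 (M3) s/mm², so the
b = 1000 s/mm² designs exist with margin and are obtained by amplitude
scaling (`scale_to_b`, which preserves nulling since moments are linear
and b quadratic in amplitude).

`rasterize_and_balance()` linearly interpolates a design to the scanner
playback raster (10 µs): the b-value of a played-out waveform must be
computed on this interpolated version. Interpolation leaves an
$O(\mathrm{raster}^2)$ residual in the integrals; only the zeroth moment
is rebalanced (a short trapezoidal pulse appended after the post-180
slot, within a 1 ms guard interval, respecting amplitude and slew
limits), mirroring what a sequence controller does. Higher-moment and
Maxwell residuals after rasterization are interpolation artifacts of the
same order and are not re-optimized; constraint verification applies to
the design-grid waveform.

## 2. The synthetic left ventricle

`phantom_spec()`/`build_lv_phantom()` construct short-axis annuli (three
slices, basal to apical, shrunk by a taper factor) at 2.3 mm in-plane
resolution with systolic wall radii 20–32 mm. Per myocardial voxel the
local frame is (radial $\hat r$, circumferential $\hat c$, longitudinal
$\hat z$); the transmural depth $d \in [0,1]$ runs endo→epi. Ground-truth
microstructure:

- **helix angle** linear in depth, $+60°$ (endo) to $-60°$ (epi);
- **tensor** with MD $1.5\times10^{-3}$ mm²/s and FA 0.34 everywhere; the
  primary eigenvector is $\hat c$ tilted by HA toward $\hat z$;
- **E2A**: the secondary eigenvector is rotated by a smooth random field
  (mean 0, SD 35°, a 2nd-order polynomial surface per slice) about the
  primary one, measured from the cross-myocyte in-wall direction toward
  $\hat r$.

Two generator choices deserve comment. First, the default eigenvalue
ratio is $\lambda_2/\lambda_3 = 1.6$ rather than an axisymmetric tensor:
with $\lambda_2 = \lambda_3$ the secondary eigenvector is undefined and
E2A cannot be recovered even noiselessly, so a package whose E2A stage
must be testable needs the asymmetry; the axisymmetric case remains
available (`l2l3_ratio = 1`). Given (MD, FA, ratio) the eigenvalues are
solved by root bracketing (`solve_eigenvalues`); note a ratio > 1 imposes
a floor on reachable FA. Second, slices are independent annuli — the
analysis is strictly per-slice, so 3-D continuity would add nothing the
pipeline could use.

`simulate_dwi()` evaluates $S = S_0 e^{-b\,\hat g^{\mathsf T} D \hat g}$
per volume for the protocol scheme (b = 100/450/1000 s/mm² in 3/30/30
directions with 12/6/6 repetitions; direction sets by seeded
electrostatic repulsion). `add_noise_and_phase()` sets the noise SD from
the target myocardial SNR at b = 100 (33 for the M2-like, 29 for the
M3-like acquisition), applies an independent smooth random phase surface
per image (2nd-order polynomial, coefficients ~ N(0, (π/2)²), a few
radians across the FOV — emulating bulk-motion phase), and adds
independent Gaussian noise to both quadratures. `inject_outliers()`
corrupts a fraction (default 2%, the discard rate seen in practice) of
images with a 0.1–0.5× dropout over a random half-plane of the
myocardium, returning truth labels. `simulate_noise_scans()` produces the
RF-disabled noise volumes (default 256 repetitions) from which the
pipeline measures σ.

What the generator does **not** emulate: EPI/susceptibility distortion
(the 18%-of-voxels exclusion masks of real data are inputs here, not
simulated), cardiac strain or through-plane motion, partial-volume blood
signal, fat, spatially varying coil sensitivity, and non-Gaussian
(time-dependent or kurtosis) diffusion. Consequently the synthetic tests
validate the *computational chain* — they demonstrate correctness of the
estimators on data obeying the stated model, not robustness to
everything an in-vivo acquisition can produce. In particular the
generator is Gaussian by construction, which is exactly why the
negative control below is meaningful.

## 3. Preprocessing

**Phase correction.** The motion phase is estimated as the argument of a
Gaussian-low-pass-filtered complex image and removed; the output is the
real part, whose noise stays zero-mean Gaussian (unlike a magnitude
image, whose Rician floor biases low-SNR shells). Two implementation
details matter. The filter kernel excludes its center voxel
(leave-one-out), so in signal-free regions the estimated phase is
independent of the voxel's own noise — otherwise the demodulated real
part is partially rectified (mean ≈ 0.25 σ instead of 0). And the
estimate is iterated twice: demodulate, re-estimate the residual,
accumulate; this removes the smoothing lag where the kernel support is
one-sided (tissue borders). The kernel width trades edge fidelity
against noise robustness: `phase_correct()` defaults to σ = 1 voxel
(noiseless magnitude recovered to < 1% under polynomial phase), while
the pipeline defaults to σ = 2 voxels, because at per-volume SNR ~ 5–10
(the b = 1000 shell) phase-estimate noise of order 1/SNR causes a small
b-dependent signal loss that a wider kernel suppresses.

**Registration.** Two-pass 2-D rigid registration per slice: low-b images
to a chosen low-b reference, then every image to the mean of the
co-registered low-b images. The metric is normalized cross-correlation
with bilinear interpolation, coarse integer-shift search plus Nelder-Mead
refinement. Three safeguards keep the stage honest on aligned data: the
metric is evaluated on slightly smoothed images (σ = 1 voxel), because
bilinear resampling at sub-voxel offsets denoises a low-SNR moving image
and thereby *raises* NCC spuriously; a transform must beat the identity
by 0.03 NCC to be applied (since NCC ≤ 1, an identity score above 0.97
is accepted immediately); and sub-quarter-voxel transforms snap to
identity. Translations beyond a quarter of the field of view flag the
volume as divergent and leave it untransformed.

**Outlier rejection.** Each (slice, image) is scored by the myocardial
mean log-signal. Scores are centered on the median of the image's
(b, direction) repetition group (≥ 4 members; otherwise the shell
median), which removes the direction dependence of the signal; the scale
is a robust SD from within-group pairwise differences pooled per shell
(median $|x_i - x_j| \times 1.4826/\sqrt2$). The pairwise estimator is
used instead of the MAD of the centered scores because centering on a
small-sample median shrinks those residuals and mis-calibrates the z
(false-positive rate ~2.5% instead of < 1% at the default cut |z| > 3).
Dropout images of the generator's kind sit at |z| in the hundreds, so
recall is not sensitive to this choice — calibration of the clean-data
tail is.

## 4. Tensor fit, noise, SNR

`fit_wlls()` fits $\ln S = \ln S_0 - b\,\hat g^{\mathsf T} D \hat g$ per
voxel: pass 1 ordinary least squares, pass 2 weighted by the squared
predicted signals (the variance-stabilizing weights for log-transformed
Gaussian data). Nonpositive real-valued signals are excluded from that
voxel's fit (never clamped; the count is reported) and voxels with fewer
than 7 usable volumes are flagged unfit. When σ from the noise scans is
supplied, the second-order bias of the log transform,
$\mathbb E[\ln(S+\varepsilon)] = \ln S - \sigma^2/(2S^2) + O(\sigma^4)$,
is removed by adding $\sigma^2/(2S^2)$ to each log-signal. At SNR ≈ 8 on
the b = 1000 shell this bias is ~0.7% of MD — invisible in any single
map but large against the Monte-Carlo precision of a slice mean, which
is why the correction is part of the default pipeline (set
`sigma = NULL` to disable).

Eigen-decomposition sorts eigenvalues descending and orients each
eigenvector deterministically (largest-magnitude component positive);
voxels with $\lambda_1-\lambda_2$ or $\lambda_2-\lambda_3 <
10^{-6}$ mm²/s are flagged degenerate and excluded from angle maps.
σ is the per-voxel SD of the real part of the RF-disabled noise scans
across repetitions (scalar summary: median); SNR maps divide the
repetition-mean signal of each (b, direction) by σ, per voxel by default.

## 5. Myocardial metrics

With the per-voxel LV frame from `local_coordinates()` (radial vector
from the per-slice center; depth by ray-traced endo/epi radii per angular
bin, circularly smoothed and interpolated):

- **HA**: project $e_1$ onto the wall-tangent $(\hat c,\hat z)$ plane;
  the signed angle from $\hat c$ toward $\hat z$, in $[-90°, 90°]$, with
  $e_1$ oriented so the projection has non-negative $\hat c$ component.
- **E2A**: with $e_1$ oriented as for HA, the cross-myocyte in-wall axis
  is $\hat c_\perp = \mathrm{normalize}(\hat r \times e_1)$; E2A is the
  signed angle of $e_2$'s projection in the $(\hat c_\perp, \hat r)$
  plane, from $\hat c_\perp$ toward $\hat r$. Orienting $e_1$ first is
  essential: without it the *sign* of E2A would flip with the arbitrary
  antipodal choice of $e_1$. Both angles are invariant to sign flips of
  any eigenvector, verified by test.
- **MD/FA** from the eigenvalues in closed form; FA of a zero tensor is
  undefined (NA), never clamped.

`summarize_roi()` reports per-slice mean ± SD for MD and FA, median and
IQR for E2A (magnitudes where the comparison convention calls for
|E2A|), and a HA histogram (10° bins over [−90°, 90°]), within the mask
minus any exclusion regions.

## 6. Scheme comparison

Per-(subject, slice) metric means are compared pairwise between the four
schemes (M2/M3 × b\_max 450/1000): Bland-Altman mean difference, SD of
differences (n−1), limits of agreement ±1.96 SD; and the two-sided
Wilcoxon signed-rank test (zeros dropped, midranks for ties, exact null
for n ≤ 25 untied differences, normal approximation with continuity
correction beyond — the exact branch is verified against an exhaustive
sign-enumeration oracle in the tests). Percentage differences are
reported relative to the first (reference) scheme's mean and rounded
only in formatted output.

## 7. Numerical choices and degenerate inputs

- γ = 2.6751525×10⁸ rad/s/T; moments use the waveform start as time
  origin (origin-invariant once lower moments are nulled).
- Maxwell tolerance default 10⁻¹⁰ (T/m)²·s — small enough that the
  concomitant phase across an 8 mm slice is negligible; configurable.
- The design grid re-quantizes slot durations to the 77-step raster so
  slot edges fall on grid points; the returned waveform carries the
  quantized timing.
- All-zero volumes pass through phase correction unchanged (with a
  warning); an all-zero noise stack yields σ = 0 with a warning and SNR
  maps are masked where σ = 0; empty ROIs raise errors rather than
  returning silent NaNs.
- Every stochastic stage takes an explicit seed and is bit-reproducible;
  the pipeline writes the resolved configuration and seed to its
  manifest.

## 8. Problem sizes used by the test suite

The suite exercises the full protocol scheme (396 volumes) on phantoms
of 48×48 voxels × 3 slices (856 myocardial voxels) for the noisy
recovery, negative-control and outlier-rejection checks (4 Monte-Carlo
replicates for the negative control, 3424 pooled voxels), reduced
designs (25–31 timesteps) for optimizer property tests, and the full
77-step, 3-restart designs for the constraint-satisfaction checks.
These sizes are the package's choice of a thorough-but-quick default;
all of them scale up by changing the corresponding arguments.

## 9. Known limitations

- The waveform optimizer is a local method with restarts; it makes no
  global-optimality claim (none is needed — all constraints are verified
  on the returned waveform, and the achieved b exceeds the protocol
  target with margin).
- Echo-time estimates are lower bounds: EPI readout timing is outside
  the designer's scope.
- Registration is 2-D rigid per slice by design; through-plane motion is
  neither simulated nor corrected.
- The negative control certifies that the pipeline does not manufacture
  a b-value dependence of MD on Gaussian data; it says nothing about the
  physiological (non-Gaussian diffusion) dependence seen in vivo, which
  is precisely what makes the in-vivo effect interpretable.
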