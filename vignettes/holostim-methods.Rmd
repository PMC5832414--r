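---
title: "Methods: hologram synthesis, focal-field simulation, and the all-optical analysis chain"
author: "holostim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hologram synthesis, focal-field simulation, and the all-optical analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holostim)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real recordings.

## The optical model

### Coordinates and the pupil grid

A square SLM of `slmPixels` pixels is mapped onto the objective pupil
with the pupil circle inscribed: pixel $(p, q)$ carries physical spatial
frequencies $(u, v)$, each spanning $[-u_{\max}, u_{\max})$ with
$u_{\max} = \mathrm{NA}/\lambda$ (cycles/µm). Two coordinate conventions
coexist deliberately:

* the **tilt** term $x_i u + y_i v$ uses physical spatial frequencies,
  so that $2\pi(x_i u)$ is an exact Fourier shift and a target at
  $x_i$ µm lands at $x_i$ µm — no calibration constant involved;
* the **Zernike** polynomials use unit-disk radii
  $\rho = \sqrt{u^2+v^2}/u_{\max}$, the convention in which their
  orthogonality and the defocus coefficient series are stated.

Mixing the two is resolved empirically: the propagation simulator acts
as referee, and the test suite verifies that a commanded
$(x, y, z)$ produces a focus at $(x, y, z)$.

The fastest representable tilt sets the addressable range
$|x| < N/(4 u_{\max})$ (about ±380 µm for the default configuration).
Targets beyond it would alias back into the field, so
`superpositionHologram` rejects them with an error naming the offending
target rather than wrapping silently.

### Defocus and spherical-aberration compensation

Refocusing by $z$ µm into a medium of index $n$ requires the pupil
phase $-z\,k_z(\rho)$ up to a constant, with
$k_z = (2\pi n/\lambda)\sqrt{1 - \sin^2\!\alpha\,\rho^2}$. The package
expresses this in the first three rotationally symmetric Zernike terms
(defocus, first- and second-order spherical aberration) with
coefficients

$$C_2^0(z) = \frac{n k z \sin^2\alpha}{8\pi\sqrt3}
  \Big(1 + \tfrac14 s + \tfrac{9}{80} s^2 + \tfrac{1}{16} s^3\Big),
\quad
C_4^0(z) = \frac{n k z \sin^4\alpha}{96\pi\sqrt5}
  \Big(1 + \tfrac34 s + \tfrac{15}{18} s^2\Big),
\quad
C_6^0(z) = \frac{n k z \sin^6\alpha}{640\pi\sqrt7}
  \Big(1 + \tfrac54 s\Big),$$

with $s = \sin^2\alpha$. These are the standard
$\sqrt{2n{+}1}$-normalized Zernike expansion of the exact defocus
phase; a unit test confirms the truncated series tracks
$-z\,k_z(\rho)$ to better than 1/100 wave at the working NA. All
coefficients are linear in $z$, so defocus masks compose linearly
before phase wrapping.

`effectiveNA` exists because on real instruments the realized axial
displacement differs slightly from the commanded one (pupil underfill,
residual system aberrations); scaling the NA inside the coefficients —
and only there — is the conventional one-knob calibration. In the clean
simulation the defaults already place foci within the package's own
acceptance bands (±1 µm lateral, ±3 µm axial), so `effectiveNA`
defaults to `na`.

### Superposition versus Gerchberg–Saxton

`superpositionHologram` takes the phase of the coherent sum of
single-target fields. It is fast, deterministic, and exact in the
weak-crosstalk limit, but discarding the sum's amplitude redistributes
some energy between targets: empirically the per-focus intensity
follows $A_i^2$ to within about 10 % (15 % is the tested bound) for
targets ≥ 20 µm apart, with the proportionality constant — not the
per-target ratio anchored to one focus — as the fitted quantity.

`gs3dHologram` is the iterative alternative for extended targets (e.g.
a 12-µm disk covering a soma). Each iteration propagates the pupil
field to every target plane with the aberration-compensated defocus
kernel (the *conjugate* of the defocus mask, since a mask that shifts a
focus by $+z$ is the inverse of propagation by $+z$), replaces
amplitudes with the target, back-propagates, sums over planes, and
re-imposes the pupil illumination. Choices left open by common practice
and fixed here:

* initial phase: uniform random from the caller's seed (bit-reproducible);
* pupil illumination: flat-top disk by default, Gaussian optionally;
* stop rule: 50 iterations or a target-correlation improvement below
  $10^{-4}$, whichever comes first; the per-iteration correlation trace
  is attached to the returned mask for auditing.

The residual zeroth-order beam is modeled as an optional unmodulated
field fraction, and the physical beam block as zeroing a configurable
central disk (default radius 5 µm) in the intermediate focal plane.

### The propagation oracle

`propagateFocalStack` uses one FFT per plane with the exact nonparaxial
$k_z$ kernel and 2× zero-padding (lateral sampling
$1/(4 u_{\max}) \approx 0.74$ µm; wrap-around suppressed). Energy per
plane obeys Parseval's identity to $10^{-6}$ relative — there are no
absorbing boundaries to hide leakage. Peak finding uses greedy
non-maximum suppression (strongest first; ties broken by lowest z, then
y, then x) and 3-point quadratic refinement per axis, clamped to half a
voxel. `fieldIntensityAt` evaluates the Debye integral directly at
continuous coordinates where grid quantization would dominate (subgrid
peak location, on-axis profiles).

Simulated, the axial two-photon PSF of the NA 0.35 / 1040 nm / water
configuration has a FWHM of ≈ 14.2 µm. A measured instrument value sits
near 14.5 µm; the two are compared at ±15 % because the measurement
includes system aberrations a clean scalar simulation deliberately
omits.

## Calibration

Burn-spot correspondences (a 7×7 grid over 240×240 µm per depth, every
25 µm of defocus) are fitted by unweighted least squares to a full 2D
affine — shear included, since the general affine subsumes it and the
fit is exact on noiseless fixtures. Between calibration depths the
matrix and offset are interpolated elementwise linearly; at a knot the
stored transform is returned bit-exactly. Beyond the calibrated range
the nearest knot is used with a warning up to a 25-µm margin, and it is
an error farther out — extrapolating a measured instrument map is not
something the package will do silently.

Diffraction efficiency decays with deflection angle. Lacking a stated
functional form, the model is separable and linear in the distances:
$\eta(x,y,z) = c_0 + c_1|x| + c_2|y| + c_3|z|$, clamped to $(0, 1]$ and
normalized to 1 at the origin. Weight compensation divides each $A_i$
by $\sqrt{\eta_i}$ so delivered power $\propto A_i^2 \eta_i$ becomes
uniform; the round-trip is verified against the simulator with the
efficiency applied as a multiplicative screen.

## Stimulation scheduling and the power budget

Spirals are parameterized uniformly in time with a linearly decaying
radius — the simplest curve consistent with "progressively shrinking
radius" — at a default 10 kHz galvo command rate; a
uniform-in-arc-length variant exists for rigs that command constant
scan speed. The sampling-adequacy precondition (≥ 10 samples per
rotation) is enforced as an error that names the required rate.

The budget arithmetic is deliberately plain: per-cell average power
$P_{ave}/M$; per-cell two-photon dose $\propto (P_{ave}/(f_{rep} M))^2$
in relative units (pulse-shape constants cancel in every comparison the
package makes); equal-dose rescaling between durations in two
conventions, constant $P\,T$ (equal energy) and constant $P^2 T$ (equal
integrated two-photon excitation). Volumetric imaging timing composes
the ~30 fps intrinsic frame rate with the 10–17 ms lens-settle wait;
the defaults (33.33 ms + 16.67 ms) reproduce the printed 6.67 vol/s for
three planes.

## Photostimulation artifact removal

Pulses arrive every $1/f_{rep}$ while pixels tick at ~8.2 MHz, so only
every $pixel\_rate/f_{rep}$-th pixel of a stimulation frame is
contaminated — a mesh. Under the resonant scan model the spacing is
modulated by the local scan-velocity profile (cosine): minimal at the
line centre, growing toward the turnaround edges, which is why the mesh
looks non-uniform. Both the detector and the synthetic generator use
the same `expectedArtifactSpacing` model, so the geometry gate is
internally consistent by construction; which direction the real
non-uniformity takes on a given rig depends on whether frames are
linearized before analysis, and the scan model is a movie-level switch.

Detection is two-stage. Stage 1 flags pixels exceeding their own
clean-frame mean + 3 SD (5 frames before and after the interval, same
imaging plane; "significantly higher" is quantified as $k_\sigma = 3$,
configurable). Per-pixel SDs from 10 frames are noisy, so they are
floored at the frame-wide median — without the floor, underestimated
SDs dominate the false-candidate budget. Stage 2 applies the geometry:
candidate runs along rows and columns no wider than 2 pixels whose
neighbour gaps match the local expected spacing within ±50 % become
*anchors*; the anchors seed the predicted pulse comb (stepping the
local spacing outward), and the final mask keeps candidates within one
pixel of the comb, splitting artifact pixels out of runs merged with
bright structure (an active cell body) up to a merge width of 6 px. A
uniformly elevated frame produces no anchors and hence an empty mask —
the signal that frame deletion, not inpainting, is appropriate.

Inpainting replaces each masked pixel with its nearest clean pixel
along the scan line (mean of both neighbours on a tie), falling back to
column neighbours for a fully contaminated line (logged). Pixels
outside the mask are bit-identical to the input and the operation is
idempotent. For short stimulations, `deleteStimFrames` drops the
affected frames instead, preserving timestamps so downstream code sees
the irregular sampling.

## Response analysis

ΔF/F changes are (stimulation mean − baseline mean)/baseline mean with
a 1 s baseline ending at onset (the conventional window is 0.5–2 s; 1 s
is the midpoint choice). A post-stimulation response window is
available for recordings where the stimulation period itself is
artifact-laden. Events require *both* the deconvolved trace and the
ΔF/F first derivative to exceed their own mean + 2 SD — each series
thresholded against its own statistics (the derivative's, not the
trace's), which makes the event train invariant under positive
rescaling of the raw fluorescence. The deconvolution stand-in is the
AR(1) inverse filter $\max(0, f_t - e^{-\Delta t/\tau} f_{t-1})$; it
exactly inverts a single-exponential transient and is replaceable by
any upstream source-extraction output.

Cells with no event in any trial's stimulation window are classified
as nonresponders and excluded from rate statistics. The ensemble
response rate is the trial-mean percentage of targeted cells
responding. Nonspecific activation is summarized as mean response
versus 3D distance to the nearest target in 10 µm bins, normalized to
the targeted-cell mean, with the half-response distance interpolated
linearly; empty bins are reported as missing, never as zero. The
orientation selectivity index is
$|(\Delta F/F|_{90} - \Delta F/F|_0)/(\Delta F/F|_{90} + \Delta F/F|_0)|$
with the sign carrying the preference; a zero denominator is flagged
undefined rather than propagated. Condition comparisons are per-ROI
two-sample t-tests (Welch), with zero-variance pairs flagged undefined.

## The synthetic generator: what it emulates and what it does not

`makeMovie` renders the structure the analysis chain assumes: cells
placed by Poisson-disk dart throwing (minimum spacing 10 µm, the lower
end of realistic somatic separations) in a 480×480×150 µm volume
snapped to imaging planes; per-trial responses drawn independently —
targeted cells at probability 0.82, non-targeted at
$p_0 e^{-d/\lambda_d}$ with $\lambda_d = 12$ µm (half-response near
$\ln 2 \cdot 12 \approx 8$ µm, inside the experimentally observed
sub-25 µm confinement); a silent fraction of 8 % that never responds; a
slow-indicator kernel (0.2 s rise, 1.5 s decay) scaled to a peak ΔF/F
near 1.3 on the cell body; Gaussian read noise; and the mesh artifact
injected only into stimulation frames with the same spacing model the
detector expects, at the 1 MHz repetition-rate condition.

It does **not** model scattering, photobleaching, motion, neuropil
contamination beyond a uniform floor, overlapping somata, spontaneous
activity, opsin kinetics, or biological trial-to-trial amplitude
variability. Passing the end-to-end tests therefore shows that the
pipeline is *self-consistent and unbiased under its own assumptions* —
that detection thresholds, geometry gates, and rate estimators recover
the generating parameters — not that those assumptions hold on any
particular recording. The trial-level binomial recovery bound (±3 SE)
is the sharpest claim the fixture licenses.

Problem sizes in the shipped tests were chosen to exercise every code
path at full fidelity while staying laptop-friendly: 256-px SLM grids
for acceptance-grade optics (the focal-grid pitch is independent of SLM
size, so accuracy is unaffected), 128-px movie frames over 3 planes and
8 trials for the analysis chain, 30-target holograms for the placement
sweep.

## Known limitations

* Scalar (non-vectorial) Debye theory: fine at NA 0.35, increasingly
  wrong above NA ≈ 0.7.
* Phase-only superposition trades per-target intensity fidelity for
  speed; for strict uniformity at large M, follow the efficiency
  compensation with a weighted-GS refinement (not implemented).
* The artifact detector assumes the mesh is sparse along scan lines
  (pixel rate ≫ repetition rate); when every pixel is hit it refuses
  and frame deletion is the supported route.
* Trace extraction averages fixed circular footprints at known
  positions; real pipelines should substitute proper source extraction
  upstream and enter the chain at `traceSet`.
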