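---
title: "Time-resolved film dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved film dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfd)
```

## The measurement problem

FLASH proton therapy delivers high doses at ultra-high dose rates
(≳ 40 Gy/s). Safety and quality assurance therefore need *time-resolved*
pre-treatment verification: not only where the dose goes, but when. For
pencil-beam scanning (PBS) the community's working quantity is the PBS dose
rate: at each position the dose-accumulation curve rises from zero to its
maximum D~max~; given a threshold d (a fraction of D~max~ or an absolute
dose), the times t~1~ and t~2~ at which the curve crosses d above minimum
and d below maximum bound the local delivery window Δt = t~2~ − t~1~, and
the PBS dose rate is ΔD/Δt with ΔD = (1 − 2d)·D~max~ (fractional d) or
D~max~ − 2d (absolute d).

`trfd` implements the analysis chain for measuring Δt with radiochromic
(EBT-XD-type) film filmed by a high-speed camera, a delivery simulator to
produce the reference Δt distribution from the plan's spot list, and a local
gamma evaluation to compare the two. Because the instrument itself (film,
light box, camera) cannot ship with a software package, `trfd` also contains
a forward model that synthesizes 8-bit camera footage from a simulated
delivery; all end-to-end claims in the test suite are made against this
synthetic instrument.

## The measurement chain

**Densitometry.** Each frame's red-channel pixel value PV maps to optical
density by standard transmission densitometry with the camera full scale as
incident intensity, `OD = log10(2^b / (PV + 1))` with b = 8. A saturated
pixel has OD 0 and OD grows as the film darkens. Each pixel is referenced to
its own pre-irradiation state: net OD is the OD change against the first
recorded frame. Net OD converts to relative dose through the fitted
calibration curve

> D(OD~net~) = a + b·OD~net~ + c·OD~net~^m^,

an empirically standard three-term form for radiochromic film. The package
fits it by profiling: for any fixed exponent m the remaining parameters are
an exact linear least-squares solve, so a one-dimensional search over
m ∈ (1, 5] finds the global optimum of the profiled residual. (A free
four-parameter Levenberg–Marquardt run on the nine-level calibration series
converges to a boundary local minimum from a neutral start, which is why the
profiled formulation is used; the fit it returns is still the plain
least-squares optimum.) Net OD slightly below zero — camera noise around
zero dose — is clipped to zero before the fractional power; values below a
tolerance of −0.02 raise an error instead.

**Coloration kinetics.** Radiochromic film keeps darkening for tens of
seconds after the dose arrives (post-irradiation coloration). The package
models the reading caused by an instantaneous unit dose deposit as the
logarithmic kernel

> k(t) = offset + c·log10(t + a),

with `a` (s) governing the fast early response and `c` the slow logarithmic
growth, and treats the measured dose trace of a pixel as the causal
convolution of the delivered pulse with k. The pulse is recovered by
deconvolution. With no regularization this is the exact solve of the
lower-triangular Toeplitz system — algebraically the same polynomial long
division used by classic signal-processing deconvolution routines —
implemented through a Newton power-series reciprocal of the kernel and FFT
convolution, so whole pixel blocks deconvolve in O(N log N) instead of
O(N²). The exact solve reproduces its input to machine precision and
amplifies measurement noise accordingly; recovered pulses may contain
negative samples and are deliberately *not* clipped (clipping would bias the
accumulation curve and hence Δt). A ridge-regularized dense solve and an
optional pre-smoothing moving average exist for noisy single curves.

One discretization choice deserves a note: the kernel is evaluated over the
*full record length*, not truncated at its nominal 60 s support. The log law
is defined for all t ≥ 0 and is still rising slowly at 60 s; truncating it
to zero would make the oldest dose deposits appear to "un-color" near the
end of any recording longer than the support (recordings are pre-roll +
beam + 60 s, so this would always happen), which showed up in development as
a mirrored tail artifact and a ~5% deficit in the stabilized dose. The
`duration_s` field keeps its meaning as the stabilization window the
recording must cover.

**Δt extraction.** The accumulation curve (cumulative sum of the recovered
pulse) is normalized to 100% using the mean of its final 1 s tail window
(240 frames at 240 fps) — the stabilized, maximum dose of that pixel. A
running-maximum envelope is applied before the threshold search:
accumulation is physically monotone, and without the envelope camera noise
would create multiple crossings and make t~1~/t~2~ ill-defined. The first
upward crossings of 10% and 90% are then located by linear interpolation
between the bracketing samples. Percentile statistics over a map (mean, 5th,
50th, 95th) use linear interpolation between order statistics, the common
default convention.

By default `trfd_analyze()` applies a 25 ms moving average (six frames at
240 fps) to each pixel's dose trace before deconvolution. This is an
analysis choice of the package: it suppresses quantization and sensor noise
at a time scale well below the multi-spot delivery windows the method aims
at (tenths of seconds), while single-spot work at the ~10 ms scale should
set `smooth_window_s = 0`.

## The delivery simulator

Spots are delivered strictly in list order. Spot i lasts `mu_i × time/MU`
seconds at a constant rate; its spatial profile is an isotropic Gaussian of
sigma 3.8 mm; its peak dose is `mu_i × (dose/MU)`, with dose/MU linear in
nozzle current because the beam monitor saturates above ~20 nA. Inter-spot
dead time defaults to zero: scanning-magnet travel data are not part of the
model, and the global linear rescaling of the simulated time axis to the
externally measured beam time absorbs the aggregate dead time instead.

Per-pixel accumulation is kept analytic — a set of piecewise-linear events —
and only sampled on demand, so the nominal 0.1 mm / 10 kHz resolution costs
nothing until a curve is materialized. The simulated Δt map is computed in
closed form by solving the threshold crossings inside the bracketing linear
segment, which is exactly what the sampled-curve procedure converges to.

The default machine constants are the package's reference synthetic
machine, chosen once at realistic magnitudes: time/MU = 1e-3 s/MU, and a
dose/MU line through (25 nA, 0.04 Gy/MU) and (215 nA, 0.06 Gy/MU), giving
0.05 Gy/MU at 120 nA. With the standard 7×7, 5 mm QA grid this yields
single-spot durations of tens of milliseconds and field delivery times of a
few seconds — the regime the method targets. The commissioning helpers
(`fit_spot_sigma()`, `commission_dose_per_mu()`, `commission_time_per_mu()`,
`field_to_spot_ratio()`) recover all of these constants from dose maps and
field-dose measurements.

## The gamma comparison

Measured and simulated Δt maps are compared with a 2-D gamma evaluation at
10% (in Δt) / 2 mm, after registering the two *dose* distributions by
normalized cross-correlation with parabolic sub-pixel refinement — dose is
the quantity with sharp, well-matched structure; Δt is what is being tested.
The gamma is local: the value criterion scales with the reference value at
each candidate point, the appropriate choice when the distribution spans an
order of magnitude and the low-Δt (high-dose-rate) regions matter most.
Candidates live on a lattice of step `distance_mm / 10` out to
3 × `distance_mm`; reference values are bilinearly interpolated; candidates
are visited in order of increasing distance and the search stops as soon as
the spatial term alone exceeds every pixel's current minimum, which is
exact. Truncating at three criterion distances cannot change any γ ≤ 1
decision, since such a candidate already contributes γ > 3. Evaluation is
restricted to the in-field region (≥ 50% isodose of the simulated dose) and
pixels whose local reference value falls below `value_floor`.

## The synthetic instrument

`synthesize_footage()` inverts the analysis chain: bin the simulated
per-pixel pulse into frame intervals; convolve with the kernel normalized to
1 at `post_roll_s`, so the stabilized response tail equals the pixel's final
dose (the same convention the tail normalization assumes on the analysis
side, making the forward model scale-consistent without an absolute-dose
calibration); convert dose to net OD through the inverse calibration curve;
add the baseline OD of unirradiated film (PV 220); convert back to PV; add
Gaussian noise (default σ = 1 PV, a conservative floor for an 8-bit
sensor); round and clip to [0, 255]. The dose→OD inversion inside the
forward model uses a dense monotone lookup table whose interpolation error
is orders of magnitude below the 8-bit quantization it feeds; the exported
`invert_calibration()` uses exact vectorized bisection (round trip better
than 1e-9 Gy).

What the synthetic instrument does *not* emulate: light-source drift,
vignetting and lens distortion, film-to-film response variation, LET
dependence, and real sensor noise statistics (read noise, fixed-pattern
noise, compression artifacts). Passing end-to-end tests therefore
demonstrate that the *analysis chain* is correct and self-consistent under
realistic quantization and noise — not that the physical instrument meets
specification; that remains a hardware QA task.

## Validation scenarios and problem sizes

The package ships three scenario generators mirroring the standard
validation protocol: single spots (Δt accuracy), revisit patterns (three
targets 15 mm apart delivered in 1, 2 or 3 equal installments; the center
target's accumulation must plateau at the expected fractions during the
pauses), and the uniform 3 × 3 cm / 5 mm QA grid for the
measurement-vs-simulation gamma comparison.

The test suite runs the full-scale gamma surrogate on a 128 × 128 camera
region at 0.14 mm pitch — 16 384 pixels × ~15 600 frames (1 s pre-roll,
~4 s delivery, 60 s post-roll at 240 fps) — once, and keeps all other
scenarios at reduced scale (shorter kernels of 2–10 s support, few-mm
camera regions, 3 × 3 grids) so the whole suite completes in minutes.
These sizes are the package's chosen validation conditions; the chain is
linear in pixels and O(N log N) in frames, so larger regions scale
predictably.

## Numerical choices and degenerate inputs

* Calibration fit: exponent bounds m ∈ (1, 5]; `0^m` defined as 0; a
  power term contributing nothing flags `m_identifiable = FALSE` instead of
  failing. Fewer than five points, or data admitting no increasing fit,
  raise errors.
* Deconvolution requires a non-zero kernel leading sample and at least two
  response samples; the pulse is returned unclipped.
* Normalization masks out (rather than errors on) pixels whose tail mean is
  not positive — unirradiated film is expected, not exceptional.
* Threshold crossings return NA when a threshold is never reached; such
  pixels are masked out of Δt maps.
* Registration refuses correlation peaks on the search boundary (no
  overlap) and degenerate all-masked overlaps.
* A pixel exactly on the gamma criterion (γ = 1) counts as passing; the
  pass-rate comparison applies a 1e-9 tolerance so the decision does not
  depend on floating-point representation of the boundary.
* Float-TIFF scalar maps store the [0, 1]-normalized field with the value
  range in the JSON sidecar (the TIFF writer clips outside [0, 1]); CSV
  maps store values verbatim.
* The bilinear reference interpolation treats any candidate with a masked
  or out-of-grid corner as invalid; an evaluated pixel needs at least one
  valid candidate, and the local reference value at the pixel itself must
  clear `value_floor`.
* Spot durations below the 3 ms machine minimum warn (the hardware cannot
  deliver them; the simulation still can).
* All randomness (footage noise) is seeded through `footage_config(seed=)`;
  identical seeds give bit-identical frame stacks.

## Known limitations

* Absolute dose is out of scope by design: TRFD yields *relative*
  accumulation, so ΔD — and absolute PBS dose rate — must come from
  conventional film dosimetry (supported via the flatbed scanner
  calibration) or an external dose map.
* The temporal resolution floor of a 240 fps camera (~4 ms/frame) biases
  Δt for single short spots; the method is intended for multi-spot fields
  whose per-pixel delivery windows are much longer.
* The coloration kernel is assumed dose-rate- and history-independent
  (linear time-invariant response); real film may deviate at extreme doses.
* The simulator models neither energy/range structure nor scanning-magnet
  travel; time scaling to a measured beam time is a global linear
  correction.
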