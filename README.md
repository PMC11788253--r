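# trfd — time-resolved film dosimetry for FLASH proton therapy QA

In FLASH proton therapy the *dose rate* is a clinical parameter in its own
right, so patient-specific pre-treatment verification has to check the time
structure of delivery, not just the dose. `trfd` implements time-resolved
film dosimetry (TRFD): a high-speed camera films the darkening of a
radiochromic film during pencil-beam-scanning (PBS) delivery, and the
footage is turned into per-pixel dose-accumulation-over-time curves, from
which the local delivery window Δt and the PBS dose rate are extracted and
compared against a simulation of the planned delivery.

The package is aimed at medical physicists commissioning or researching
UHDR/FLASH proton beams who need a desk-verifiable implementation of the
full analysis chain.

## What it computes

For each camera pixel with 8-bit red-channel value PV:

1. **Densitometry** — optical density `OD = log10(2^b / (PV + 1))`, net OD
   against the first (pre-irradiation) frame, and relative dose through the
   fitted calibration curve `D = a + b·OD_net + c·OD_net^m`.
2. **Coloration correction** — radiochromic film keeps darkening after the
   beam stops. The reading is modelled as `response = pulse ⊛ k` with the
   film-response kernel `k(t) = offset + c·log10(t + a)`; deconvolving k
   (exact triangular-Toeplitz solve via an FFT Newton reciprocal) recovers
   the delivered pulse, whose running integral is the dose-accumulation
   curve.
3. **Δt / PBS dose rate** — each curve is normalized to 100% on its final
   1 s tail; the 10% and 90% crossings t₁, t₂ (linear interpolation under a
   running-maximum envelope) give `Δt = t₂ − t₁`, and the PBS dose rate is
   `ΔD/Δt` with `ΔD = (1 − 2d)·D_max` for threshold d.
4. **Delivery simulation** — spot lists (x, y, MU per line, delivery order =
   line order) are simulated as sequential Gaussian spots (σ = 3.8 mm,
   dose/MU linear in nozzle current, constant time/MU), analytically as
   piecewise-linear accumulation events, optionally rescaled to a measured
   beam time.
5. **Comparison** — measured and simulated Δt maps are registered on their
   dose distributions (normalized cross-correlation, sub-pixel) and compared
   with a **local 2-D gamma evaluation** (10% / 2 mm) over the in-field
   (≥50% isodose) region.

A synthetic-footage forward model (coloration kinetics → 8-bit quantization
→ pixel noise) stands in for the camera/film instrument so the whole chain
can be validated end to end without hardware.

## Worked example

Simulate the standard 7×7 QA grid, synthesize noisy footage of it, run the
measurement chain, and verify measurement against simulation:

```r
library(trfd)

cal     <- calibration_params(a = -7.48e-3, b = 24.5, c = 33.5, m = 1.80)
rf      <- response_function(offset = 7.5e-3, a_shift = 5.4e-2,
                             c_slope = 5.7e-4)   # coloration kernel
machine <- machine_model()                        # sigma 3.8 mm, 1e-3 s/MU

spots <- scenario_qa_grid(field_mm = 30, spacing_mm = 5,
                          total_dose_gy = 15, current_nA = 120,
                          machine = machine)
sim   <- simulate_delivery(spots, machine, nozzle_current_nA = 120)
sim
#> <trfd_sim> 49 spots, beam time 4.05 s, grid 610 x 610 @ 0.1 mm, sigma 3.8 mm

cam   <- sim_grid(128 * 0.14, 0.14)               # 128 x 128 camera region
stack <- synthesize_footage(sim, cal, rf,
                            footage_config(noise_sigma_pv = 1, seed = 17),
                            grid = cam)
stack
#> <trfd_frame_stack> 15593 frames of 128 x 128 px @ 240 fps (65 s), pitch 0.14 mm
#>   beam start at frame 241

ana  <- trfd_analyze(stack, cal, rf)              # PV -> OD -> dose -> pulse -> delta-t
dtm  <- sim_delta_t(sim, grid = cam)              # ground-truth delta-t map
dose <- final_dose_map(sim, cam)
reg  <- register_maps(ana$dose, dose)
gam  <- local_gamma(shift_map(ana$delta_t_map, reg$dx_mm, reg$dy_mm), dtm,
                    gamma_criteria(0.10, 2.0), mask = infield_mask(dose))
gam
#> <trfd_gamma> 99.3% pass (gamma <= 1) over 16129 pixels [10% / 2 mm, local]

delta_t_statistics(ana$delta_t_map, infield_mask(dose))
#> # A tibble: 1 × 5
#>    mean    p5   p50   p95     n
#>   <dbl> <dbl> <dbl> <dbl> <int>
#> 1  1.08 0.634  1.17  1.20 16384
```

The pass rate says 99.3% of in-field pixels agree with the planned time
structure within 10% in Δt or 2 mm in position; the statistics table gives
the Δt distribution (here a mean per-pixel delivery window of ~1.1 s for
this 4 s field). `trfd_verify()` wraps steps analyze→simulate→register→
gamma→statistics into one call returning a pass/fail report, and
`inst/cli/trfd.R` exposes the same steps as shell subcommands
(`fit-calibration`, `simulate`, `synthesize`, `analyze`, `gamma`, `verify`,
`make-scenario`).

Fitted objects follow broom conventions (`tidy()`, `glance()`), maps have
`autoplot()` methods, and all on-disk formats are plain text or
PNG/TIFF + JSON sidecars.

## Scope

Relative dosimetry only: absolute dose (and hence absolute PBS dose rate)
is deliberately out of scope — the ΔD component comes from conventional
film dosimetry, for which the flatbed-scanner 2-D calibration
(`fit_scanner_calibration()`) is included. Camera control, video decoding
and LET corrections are likewise out of scope; frames are assumed
pre-extracted to single-channel images.

See `vignettes/trfd-methods.Rmd` for the models, parameter choices, and
known limitations.
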