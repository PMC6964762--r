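---
title: "Methods: spot-halo characterization and field size factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-halo characterization and field size factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbshalo)
```

## The problem

A proton pencil-beam-scanning (PBS) spot is not a single Gaussian. Around the
narrow core sits a broad, low-intensity *halo* — for low energies generated by
large-angle scattering in the treatment head and in air — that carries only a
few percent of the fluence but extends to several core widths. A treatment
planning system (TPS) that models each spot as one Gaussian therefore predicts
essentially no dose beyond roughly 2.6 times the FWHM (the 1% isodose of a
Gaussian), while real spots deliver measurable dose well beyond that. Summed
over the thousands of spots of a scanned field, the missing halo shows up as
an overestimate of the central dose of *small* fields: the field size factor
(FSF) — central dose of a square field relative to the 10 cm field — is
mispredicted by several percent at low energy.

Quantifying this requires measuring spot profiles over four decades of
intensity (down to 0.01% of the peak), which exceeds the dynamic range of both
radiochromic film (useful range about 0.01–8 Gy) and scintillator-CCD imagers
(0–1000 counts). The *pair-magnification* technique overcomes this by pairing
successive irradiations at increasing dose — here 1x, 20x and 400x — and using
the higher exposures, after registration, for the fainter regions.

This package implements the full chain: a synthetic measurement generator, the
compositing step, radial profile and width analysis, and the FSF
superposition; it ships the published reference width and FSF-error tables it
is calibrated against (`reference_spot_widths()`,
`reference_fsf_percent_errors()`).

## Spot model and synthetic data

The generator's truth is the peak-normalized two-Gaussian mixture

$$ f(r) = (1 - w)\,e^{-r^2/2\sigma_c^2} + w\,e^{-r^2/2\sigma_h^2},
\qquad 0 \le w < 1,\ \sigma_h > \sigma_c , $$

rendered on a grid of 0.5 mm pitch (the scintillator-CCD resolution; scanner
pitch for film is not separately modeled) extending to $5\sigma_h$.
`spot_model_from_widths()` chooses $(\sigma_c, \sigma_h)$ at fixed $w = 0.05$
so that the profile passes exactly through a requested FWHM and FW1% — the
bundled film values at the isocenter serve as per-energy defaults
(`default_spot_models()`). Two modelling notes:

* **Halo weight.** The reference tables constrain two widths, not three
  mixture parameters; $w = 0.05$ is fixed at a value typical of published
  in-air double-Gaussian parametrizations and is not fitted.
* **Sub-Gaussian high energies.** Above roughly 150 MeV the measured
  FW1%/FWHM ratio at the isocenter falls *below* the Gaussian value
  $\sqrt{\ln 100/\ln 2} = 2.5776$ (e.g. 19.7/8.7 = 2.26 at 242 MeV). No
  nonnegative mixture with $\sigma_h > \sigma_c$ can reproduce that, so the
  fit falls back to a pure Gaussian matched to the FWHM and the FW1% request
  is ignored. The halo physics this package targets is the low-energy regime,
  where the mixture fits both widths.

Device degradation is parametric (`device_model()`): the magnification-1
exposure is scaled so its peak reads 6 Gy on film (saturation 8 Gy) or 800
counts on the scintillator (saturation 1000) — headroom mirroring measurement
practice; readings above saturation are clamped and flagged, exactly;
per-pixel multiplicative Gaussian noise of relative scale 0.001 is applied
with a per-exposure seed. The scale 0.001 is the value consistent with the
composite-uncertainty budget of the technique (see below).

The scintillator over-response is modeled as a multiplicative factor on the
+y half of the image only, ramping linearly in $\log_{10}$ relative intensity
from 1 at or above 10% of the peak to $1 + 0.4$ at or below 1%. Direction,
maximum and low-dose growth reflect the observed artifact; the ramp *shape*
is a modelling choice — the true intensity dependence is not published — and
only its endpoints matter to the analysis, because the angular mask removes
the affected region entirely.

What the generator does **not** emulate: film-chemistry or CCD-optics blur,
spatially correlated noise, lattice misalignment of the scanner, beam-size
drift between exposures. Passing tests therefore demonstrate correctness of
the *analysis* under the stated statistical model, not robustness to every
systematic a physical measurement can exhibit.

## Pair-magnification compositing

`register_exposures()` aligns each exposure to the first by maximizing the
normalized cross-correlation over mutually trusted pixels (unsaturated and
below 0.8 of saturation) on an integer-pixel search grid (default ±3 mm),
refined to sub-pixel precision by a parabolic fit through the correlation
peak in each axis. On noiseless synthetic shifts the recovered offsets are
accurate to a few hundredths of a pixel; the tests require 0.1 mm.

`compose()` then applies the level-selection rule: each pixel takes its value
from the **highest-magnification exposure in which it is trusted**, divided
by that exposure's magnification. Trust ends at 0.8 of saturation rather than
at saturation itself so that near-clipped, nonlinear readings are excluded;
between half the trust limit and the trust limit adjacent levels are
cross-faded with weights linear in the raw reading, which makes the composite
exactly continuous across level transitions on noiseless input (on noiseless
input it equals the truth pixel-for-pixel — one of the test oracles). The
result is peak-normalized to 1 over valid pixels; pixels trusted in no
exposure are flagged invalid rather than erroring. Whether physical
implementations of the technique blend or switch hard between exposures is
not documented; continuity is the requirement that drove the cross-fade.

**Fidelity statistic.** The technique's accuracy claim is a *relative
uncertainty*: 0.2% down to signal levels of 0.01% of the peak. The package
measures it as the RMS of $(\text{composite}-\text{truth})/\text{truth}$ over
pixels with truth $\ge 10^{-4}$ of the peak; on seeded synthetic sets this is
0.10–0.17% (mean ≈ 0.13% over ten seeds), dominated by the per-pixel noise
(0.1%) plus the noise of the single peak-normalization pixel. The *maximum*
pointwise error is not a meaningful fidelity measure here: over the
$\sim 1.4 \times 10^4$ qualifying pixels the maximum of iid relative noise
concentrates near $\sqrt{2\ln n}\,\sigma \approx 4\sigma \approx 0.4$–0.5%
for *any* unbiased noise of scale 0.1%, which is why the tests bound the RMS
at 0.2% and the extreme pixel only at 1%.

`dynamic_range()` (peak over smallest positive valid intensity) documents the
reach of a composite; the 1/20/400 series extends it beyond $10^4$, i.e. past
the 0.01% level that single exposures cannot reach.

## Radial profiles and widths

`to_radial()` converts a composite to polar coordinates about the fitted
center (`find_center()`: intensity-weighted centroid of pixels within the top
5% of the range) and averages over the pixels whose polar angle falls in a
chosen interval, in 0.5 mm bins (the pixel pitch; widths are then resolved to
about one bin).

Conventions, each a deliberate choice:

* **Angle origin.** Polar angle is measured from the **+y axis** — the
  direction of the scintillator over-response (the camera-neck side) —
  increasing clockwise. The standard artifact-free interval `c(135, 225)` is
  then the quarter *opposite* the neck, which contains no contaminated pixel
  of the +y half-plane artifact; film images use the full circle. (With the
  common 0°-along-+x convention, an interval written 135–225° would straddle
  the contaminated half-plane — the angle origin is what makes the quarter
  mask consistent.)
* **Peak normalization.** Profiles are renormalized by the count-weighted
  mean of the bins within 1 mm of the center, not by the single peak pixel,
  to reduce single-pixel noise sensitivity. For a 0.5 mm-binned Gaussian of
  clinical size this inflates widths by well under a bin.
* **Center pixel.** The exact center pixel (radius 0, undefined angle) is
  excluded; this also makes any 90°-aligned quarter average *identical* to
  the full-circle average for symmetric spots, a property the tests exploit.
  Pixels exactly on an interval boundary belong to the interval they start
  (angles rounded to 1e-9 degrees before the comparison).
* **Width extraction.** `width_at_fraction()` scans outward from the peak bin
  and linearly interpolates the *first* crossing of the requested level
  (inside-out). Widths are therefore well defined even if noise produces a
  second crossing further out. `sigma_from_fwhm()` is the exact Gaussian
  relation $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$.

`compare_devices()` reproduces the standard film-vs-scintillator comparison
layout: per-energy raw difference (mm) and percent difference with the second
device in the denominator, plus their arithmetic means (the printed Mean row,
at one decimal, is the reproducible surface of such tables; per-row printed
values reflect unrounded underlying data).

## Field size factors

`spot_positions()` lays out the square lattice: `round(side/spacing)`
intervals per axis, symmetric about the field center, so the delivered side
is the interval count times the 2.5 mm spacing (nominal 32 mm becomes
32.5 mm) and a spot sits at the origin for even counts — matching
centered delivery with a detector at the field center. `central_dose()` sums
the kernel over the lattice at the center point, or averages that sum over a
2 mm-radius disc sampled on a deterministic uniform grid (0.2 mm) to emulate
a small ion chamber. The chamber is a sphere in reality; the profiles here
are 2D in-air images, so in-plane disc averaging is the appropriate
surrogate, and for the flat center of a 10 cm field the effect is far below
the 0.3% bound quoted for chamber volume averaging.

`fsf_curve()` normalizes central doses to the 10 cm field. Two kernel routes
exist deliberately: the analytic single-Gaussian (TPS surrogate) and the
grid kernel built from a composite (bilinear interpolation, zero outside the
measured support — a warning reports fields whose tails are truncated). The
closed form

$$ \mathrm{FSF}(L) =
\frac{\operatorname{erf}^2\!\big(L / (2\sqrt{2}\,\sigma)\big)}
     {\operatorname{erf}^2\!\big(L_{\mathrm{ref}} / (2\sqrt{2}\,\sigma)\big)} $$

is the fine-spacing limit used as an independent oracle; a lattice of $n+1$
spots at spacing $d$ spans $nd$ but is the midpoint rule for an integral over
$(n+1)d$, so lattice results are compared to the closed form at that
effective side (at nominal sides the comparison would be off by ~1% for a
20 mm field at $\sigma = 3.7$ mm; at effective sides it agrees to <0.1%).
Replacing the matched single Gaussian by a halo-bearing kernel (renormalized
to peak 1) strictly lowers the FSF below the normalization side — the sign of
the TPS overestimate — because the halo's capture ratio between the small and
the 10 cm field is smaller than the core's.

## Numerical choices and problem sizes

* Bilinear interpolation error is bounded by $p^2 |f''| / 8$; at the 0.5 mm
  pitch this is $\le 0.1\%$ of peak for clinical spot sizes
  ($\sigma \gtrsim 5$ mm) and grows quadratically for the deliberately tiny
  kernels some tests use ($\sigma = 2$ mm: ~0.8%), which is reflected in
  their tolerances.
* Registration search radius defaults to ±3 mm (±6 pixels); parabolic
  refinement is skipped at the search boundary.
* The test and acceptance workloads use single spots on 121–189 pixel grids,
  three-exposure sets, and ten-seed ensembles — sizes chosen so the full
  suite runs in seconds while every statistic quoted above is computed, not
  assumed.
* All randomness flows through explicit integer seeds (one per exposure);
  rendering saves and restores the global random state.

## Known limitations

* The generator's noise is iid multiplicative; real film grain and CCD shot
  noise are neither iid nor purely multiplicative, so the composite
  uncertainty attained here is a best case of the statistical model.
* Grid kernels truncate the halo at the measured extent; FSFs of fields
  larger than the measured support inherit a small positive bias at small
  sides (the normalization field loses more tail than the small field).
* Everything is in-air at the measurement plane: no depth-dependent halo, no
  range-shifter effects, no absolute dosimetry.
* The absolute reference FSF curve of the ion-chamber measurements is not
  published (only percent errors are), so the pipeline's Table-4-style output
  compares the Gaussian surrogate against the halo kernel rather than against
  a reconstructed chamber curve.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(list(energies = 70, positions = "Z0", seed = 1,
                       output_dir = tempfile("run")))
res <- run_pipeline(cfg)
res$widths           # film/lynx FWHM, FW10%, FW1%, sigma at 70 MeV
res$fsf$error        # Gaussian surrogate vs halo kernel, percent error
```
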