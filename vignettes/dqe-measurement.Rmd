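---
title: "Measuring detector DQE: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring detector DQE: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqemam)
```

## The measurement model

The detective quantum efficiency of a digital X-ray detector compares the
information content of its output to that of the incident quantum field:

$$\mathrm{DQE}(u,v) \;=\; \mathrm{MTF}^2(u,v)\,
\frac{W_\mathrm{in}(u,v)}{W_\mathrm{out}(u,v)},
\qquad W_\mathrm{in} = \mathrm{SNR}^2_\mathrm{in}\cdot K .$$

The three ingredients are measured independently and only combined at the
end, which is why the package keeps them as separate stages with their own
containers and diagnostics.

**Signal transfer property (STP).** All frequency-domain analysis operates
on *linearized* data: raw pixel values are mapped to input photon fluence
(mm^-2^) through the inverse of a fitted affine conversion. The fit is
ordinary least squares of mean pixel value on air kerma at the detector
(KAD); the kerma measured at a tabletop meter is first referred to the
detector plane by the inverse-square law
$(d_\mathrm{chamber}/d_\mathrm{detector})^2$. The fit is unweighted — the
calibration points come from the same detector at similar noise levels, and
no weighting scheme is standardized for this use — and the intercept is
retained: linearity is enforced through the compliance gate
$R^2 \ge 0.99$, not by forcing the line through zero. A non-compliant fit
is returned with a warning rather than an error so the data can be
inspected; `linearize()` refuses it unless explicitly overridden. The
fluence basis uses $Q = \mathrm{SNR}^2_\mathrm{in}\cdot K$, so the shipped
beam-quality table (`inst/extdata/snr_in2_table.tsv`, editable plain text)
is the single source of the SNR^2^~in~ constant; unknown anode/filter/kVp
combinations are *never* interpolated — the user must supply a tabulated
value.

**Noise power spectrum.** The 2-D NPS is estimated by periodogram averaging
over 256×256-pixel ROIs tiled with 128-pixel overlap across a 50 mm × 50 mm
analysis region of each flat-field image:

$$W(u_n,v_k) = \frac{\Delta x\,\Delta y}{M\cdot 256^2}
\sum_{m=1}^{M}\bigl|\mathrm{DFT}_2[\,I_m - S\,](u_n,v_k)\bigr|^2 .$$

The implementation uses `stats::fft()` but is verified in the test suite
against the literal double sum, frequency pair by frequency pair, on
reduced grid sizes (4, 8, 16) to a relative tolerance of 1e-12. Directional
1-D spectra average the 14 lines nearest each frequency axis, excluding the
axis itself; the zero-frequency value is reported separately because its
magnitude is purely a consequence of the detrending convention. NNPS
divides by the squared mean of the linearized data, so for an ideal Poisson
field at fluence $Q$ the NNPS is $1/Q$ — a property the tests exploit.

**Trend removal.** The subtracted surface $S$ may be nothing, the global
mean of the region, or a total-degree-2 polynomial (six coefficients)
fitted once per image over the full analysis region — not per ROI, since
the large-scale trend is a property of the flat field, and a per-ROI fit
would spend 6 of 65 536 degrees of freedom per tile on noise. Subtracting
any constant changes only the zero-frequency bin of each ROI periodogram;
the suite checks that `mean` and `none` agree bin-for-bin off the axis to
round-off, which is why `mean` is a safe default: it costs nothing
spectrally and removes the bulk offset.

**Slanted-edge MTF.** The edge is located per line by the centroid of the
absolute discrete gradient (restricted to a window around the gradient
peak), a straight line is fitted to the crossings, and
$\alpha = \arctan(\mathrm{slope}\cdot\Delta x/\Delta y)$. The calculation
window is split into consecutive sections of $N = \mathrm{round}(1/\tan\alpha)$
lines; because $1/\tan\alpha$ is not an integer in general, samples are
*re-registered* within each section by their perpendicular distance to the
fitted edge and binned at $h = \Delta x/N$, rather than truncating lines.
Per-section ESFs are averaged bin-wise, which suppresses noise without
mixing sections that see the edge at different sub-pixel phases. The LSF is
the central difference $[-0.5, 0, +0.5]/h$; its Fourier magnitude is
normalized at zero frequency, the frequency axis is scaled by $\cos\alpha$
to refer to the detector axis, and each value is divided by the
differentiation kernel's exact response $\sin(2\pi f h)/(2\pi f h)$ (limit
1 as $f \to 0$). Finally the curve is averaged into the NPS frequency bins
(half-open on the upper edge) and truncated at Nyquist, with the zero bin
pinned to 1.

**DQE and uncertainty.** The ratio is formed only on the shared NPS grid —
no silent resampling — and additionally binned at multiples of 0.5 lp/mm
(mean over ±0.25 mm^-1^, upper edge open), stopping at Nyquist; at
0.085 mm pitch that is 5.88 mm^-1^ and the last bin centre is 5.5. No
polynomial smoothing is applied to DQE: binning is the only aggregation,
and the report carries the raw grid too. The combined relative uncertainty
is the GUM root sum of squares with the MTF term doubled (DQE depends on
MTF squared); the W~out~-labelled middle term is populated from the
user-supplied input-spectrum accuracies — kerma-meter accuracy and the two
distance errors, the latter doubled by the inverse-square law — because
those are the quantities a user can actually state. The NPS term is
$1/\sqrt{M\cdot\mathrm{row}\cdot\mathrm{bin}}$ with row = 14 and *bin* the
number of raw frequency samples averaged into each reported value, which
matches periodogram-averaging statistics and makes the term dimensionless.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| analysis region side | 50 | mm | one region holds 3×3 overlapping ROIs at typical mammography pitches |
| ROI size / step | 256 / 128 | px | fixes the frequency grid $n/(256\,\Delta x)$ |
| lines averaged per axis | 14 | — | ±7 lines, axis excluded |
| minimum pixels | 4×10^6^ | px | `required_image_count()`; 12 images at 0.085 mm pitch |
| trend method | `mean` | — | spectrally free off-axis; `poly2` available for strong trends |
| edge window half-width | 20 | px | covers the LSF support of PSFs up to σ ≈ 0.5 mm-equivalent while limiting noise |
| LSF taper | on | — | zero tails where \|LSF\| < 0.1% of peak for 10 consecutive samples |
| fine-grid spacing bound | 0.01 | mm^-1^ | LSF zero-padded so every NPS bin receives samples |
| u~MTF~ scale `c` | 0.4 | — | `c/sqrt(n_lines)` ≈ 2% for a 400-line window |
| compliance gate | 0.99 | — | the standardized R² bound |

## What the synthetic model emulates — and what it does not

`detector_model()` is a forward model of the estimated quantities, which is
what makes every stage testable against exact ground truth:

- *Flat fields*: per-pixel quanta counts $n \sim \mathrm{Pois}(Q\,\Delta
  x\,\Delta y)$ with $pv = \mathrm{offset} + \mathrm{gain}\cdot
  n/(\Delta x \Delta y)$, so the linearized image is an ideal Poisson
  fluence field with white NPS equal to $Q$; optional Gaussian PV noise and
  multiplicative plane/quadratic trends.
- *Edges*: an ideal step at a known angle, blurred by a Gaussian PSF and
  integrated over the pixel aperture *analytically* (differences of
  $\int\Phi$), never by supersampling — the recorded ground-truth MTF
  $e^{-2\pi^2\sigma^2 f^2}\,|\mathrm{sinc}(\pi f \Delta x)|$ is exact, not
  itself an estimate. With `aperture = FALSE` the profile is point-sampled,
  which removes the sinc factor and makes the *ideal* detector — DQE = 1
  at every frequency — constructible: a Poisson detector with a real pixel
  aperture has white NPS but sinc-shaped MTF, so its true DQE is
  $\mathrm{sinc}^2$, and only the aperture-free variant isolates the
  chain's accuracy from detector physics.
- *Calibration series*: mean pixel value exactly affine in kerma, with
  ground-truth slope and intercept recorded.

Real data differ in ways the model deliberately omits: scatter and glare,
structured/fixed-pattern noise beyond a smooth trend, detector lag,
non-Poisson cascaded gain stages, and edge-device imperfections
(non-straight edges, transmission through the plate). Passing tests
therefore demonstrate that the *estimators* are correct and stable under
quantum-limited conditions — not that any particular clinical detector
will show these numbers.

Quantization to integer pixel values is part of the model (`quantize`,
default on). At the default working point its variance contribution
(1/12 PV²) is about 10^-6^ of the quantum noise power; the zero-noise
analytic checks disable it.

## Numerical choices and degenerate inputs

- ROI tiling anchors at the region origin; leftover margin stays at the far
  edge. Deterministic tiling makes repeated runs bit-identical.
- Region extraction defaults to image-centred placement; a chest-wall
  anchored mode (lateral centring, configurable offset from the chest-wall
  border) is provided since protocols differ, but neither is claimed
  canonical.
- `poly2` fitting uses centred, scaled coordinates so the normal equations
  stay well conditioned on 588×588 regions.
- Edge detection declares failure when more than 10% of lines show no
  clean monotone step (flat images, double edges); angles outside
  (0.5°, 45°) warn, and angles so small that $1/\tan\alpha$ exceeds the
  window height abort the ESF stage — oversampling is impossible there.
- Sub-pixel bins empty in *every* section (possible when $1/\tan\alpha$ is
  far from integer) are filled by linear interpolation; bins empty in some
  sections simply average over the sections that cover them.
- Dark-to-bright edges are flipped so the ESF always ascends; the MTF is
  polarity-invariant by construction and by test.
- The differentiation-kernel correction is cut off where the kernel
  response falls below 0.1 in magnitude — far beyond the detector Nyquist
  for any admissible angle — to avoid amplifying the response zero.
- `bin_dqe` and `rebin_mtf` raise errors naming the first empty bin rather
  than returning NA curves.
- KAD can be supplied (measured kerma × geometry factor) or, when absent,
  derived from the flats through the inverse conversion function; for the
  synthetic model both routes agree by construction and the test suite
  checks it.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on generated data:
12 flat fields of 620×620 px (108 overlapping ROIs over the 50 mm region),
edge images of 840×300 px (≈36 sections at 2.5°), and 512×512 white-noise
fields (54 ROIs) for the spectral calibration checks. These sizes give
per-bin NPS statistics of ~2.6% ($1/\sqrt{108\cdot 14}$) so that the
end-to-end DQE of the ideal study stays within ±0.05 per 0.5 lp/mm bin,
while the whole suite completes in well under a minute.

## Known limitations

- Only square-ish pixel geometries are fully exercised; with
  $\Delta x \neq \Delta y$ the x and y spectra live on different frequency
  grids, and the combined CSV report uses the x grid for both.
- DICOM support covers uncompressed single-frame monochrome Explicit VR
  Little Endian — the "for processing" exports this chain needs.
  Multi-frame, compressed or "for presentation" images are refused, not
  corrected.
- The MTF uncertainty is a declared heuristic scale
  ($c/\sqrt{n_\mathrm{lines}}$), monotone in the information used but not a
  first-principles estimator; calibrate `c` locally if a validated figure
  is needed.
- SNR^2^~in~ values are tabulated inputs; the package does not compute them
  from spectra.
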