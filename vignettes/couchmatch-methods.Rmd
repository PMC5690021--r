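---
title: "Measuring residual patient-positioning error with weighted block matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring residual patient-positioning error with weighted block matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In image-guided radiotherapy — particularly particle therapy, where dose
placement is sensitive to the water-equivalent path length through bone —
patient setup is verified just before irradiation by comparing orthogonal
treatment-room radiographs (DR, frontal and lateral) against digitally
reconstructed radiographs (DRR) projected from the planning CT. The residual
misalignment is traditionally measured by hand: technicians "point" at
corresponding bony landmarks on DR and DRR and read off their distance. That
is slow and observer-dependent. `couchmatch` implements an automatic
replacement: a block-matching registration of each view, with the two views'
image displacements combined into couch-space (lateral / vertical /
longitudinal) errors.

## The registration model

For each view, a calculation window `w` of side `N = round(s * sn)` pixels
(image side `s`, fraction `sn`) is centered on the planned isocenter. For a
candidate offset `d = (dx, dy)`, both images are weighted by an
isocenter-centered Gaussian evaluated at the displaced position,

    w(p + d) = exp(-((x_ic - x - dx)^2 + (y_ic - y - dy)^2) / (2 sigma^2)),
    sigma = N * s_sigma,

so that agreement near the beam axis counts more than agreement at the
periphery — mirroring how technicians weight their judgement, and insulating
the match against peripheral soft-tissue change. The similarity at `d` is the
zero-mean normalized cross-correlation (ZNCC) of the weighted intensities

    I'_DRR(p + d) = I_DRR(p + d) w(p + d),   I'_DR(p) = I_DR(p) w(p + d),

with means taken over the contributing window pixels and the standard ZNCC
denominator (the root of the product of the two centered sums of squares), so
`R` lies in [-1, 1] and is invariant to intensity gain. Collimated and
out-of-bounds pixels are excluded from all sums rather than zero-filled, so
blocked regions cannot bias the means; a candidate with fewer than
`min_valid_px` contributors, or zero variance on either side, is *undefined*
(an `NA` sentinel) and skipped.

The best match maximizes `R` over integer offsets, then refines on a
fractional grid of pitch `subpixel_step_px` within ±1 px of the integer
peak, sampling the DRR by bilinear interpolation. Ties break toward the
smallest offset norm, then row-major order, so the result is deterministic.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `s` | 480 | px | nominal image side used to size the window |
| `sn` | 0.8 | – | window fraction; `N = round(s * sn)` |
| `s_sigma` | 0.4 | – | Gaussian width as fraction of `N` (`sigma = 153.6` px at defaults) |
| `M` | 40 | px | search radius: integer candidates span `[-M, M]` per axis |
| `mt` | 30000 | 16-bit units | Sobel threshold for the field-edge scan |
| `subpixel_step_px` | 0.05 | px | refinement pitch (≈ 0.022 mm at 0.446 mm/px) |
| `pixel_spacing_mm` | 0.446 | mm/px | physical pixel size |
| `min_valid_px` | 16 | px | minimum contributors per candidate |

**Why `M` is a radius.** The couch-shift evaluation pattern reaches ±10 mm,
which is ±22.4 px at 0.446 mm/px. A 40-px-wide candidate window (±20 px)
could not contain it, yet the published experiment recovers those shifts, and
the physical window sizes quoted alongside `M` values do not match
`M × 0.446 mm` either (the capture magnification evidently differed). We
therefore interpret `M` as the search radius: candidates span `[-M, M]`,
i.e. ±17.8 mm at the default spacing, which covers the full pattern with
margin. A peak on the border of that grid sets a `border_peak` warning flag,
signalling that the true displacement likely exceeds the search radius.

## Preprocessing

Captured positioning images carry rendered decorations (target-volume
contour, axes, grid ticks, pointing marks and labels). They are detected by
color match against a configurable palette (per-channel tolerance) — the
saturated palette colors cannot collide with grayscale anatomy — and filled
by iterative 8-neighbor averaging: each flagged pixel takes the mean of its
non-flagged neighbors, and thick annotations resolve over repeated passes
(onion peel). This matches the neighborhood-interpolation description
literally and is deterministic; we deliberately did not solve a Laplace
system, whose result would differ imperceptibly but cost more to verify.

The collimator-blocked border is then masked: the Sobel gradient magnitude
(Euclidean combination of the two 3×3 responses, edge-replicated borders) is
scanned row-wise from left and right and column-wise from top and bottom;
pixels outside the first magnitude exceeding `mt` are blocked, and the final
mask is the union of the four scans. Two consequences are worth knowing.
Corner blocks whose rows and columns contain no edge are unreachable by any
scan and stay unmasked — harmless, because they also lie outside the
isocenter-centered window. And a field collimated on one side only will have
its far side blocked too, because the single field edge is also the first
edge "from the far side"; the method presumes a field framed by edges, as
clinical DRs are. Intensities are handled on a 16-bit scale so the printed
threshold `mt = 30000` is meaningful; for 8-bit inputs the config rescales
it by 1/257.

## From image displacements to couch errors

The frontal x-axis maps to the lateral couch axis, the lateral x-axis to the
vertical axis, and both y-axes to the longitudinal axis. With reference
displacements taken from the registration at the zero couch position, the
per-pattern errors are

    E_lat  = m_lat  - (dxF_ref - dxF_i)
    E_vert = m_vert - (dxL_ref - dxL_i)
    E_long = m_long - ((dyF_ref - dyF_i) + (dyL_ref - dyL_i)) / 2

(all converted to mm), and the per-pattern RMSE is the root of the mean of
the three squared errors. Aggregates use the *population* SD (divisor `n`):
that convention reproduces the published summary row (mean RMSE 0.23, SD
0.05) exactly, while the sample SD does not. Internally everything is kept
at full precision; 2-decimal rounding is applied only for display. One
rounding artifact is documented: the published pattern-1 row RMSE (0.14) is
not reproducible from its printed per-axis errors, which give 0.1455 → 0.15;
the published value was evidently aggregated before rounding. Rows 2–10
reproduce exactly.

The reported displacement is the offset applied to the DRR that best overlays
it on the DR, so a couch correction equals the negated report.

## The synthetic phantom

Since the physical pelvic phantom and clinical images are unavailable, the
package generates its own study conditions: a procedural pelvic-like scene
(soft-edged rings, ellipses and bars over a graded background — pelvic brim,
femoral heads, iliac wings, sacrum) rendered per view, with the lateral view
contrast-compressed (`lateral_contrast = 0.7`) to mimic its longer
transmission path. The DR is the DRR translated by the view-mapped couch
shift (bilinear resampling for fractional pixel shifts — the same resampling
the matcher's refinement uses, so noiseless recovery bias is bounded by
interpolation symmetry, not model mismatch), intensity-transformed
(`gain = 1.05`, `offset = 300`), degraded with additive Gaussian noise,
collimated by zeroed border bands with a sharp field edge, and decorated
with palette-colored overlays. All randomness derives from the single spec
seed, and every painted/blocked pixel is recorded as ground truth.

**Noise calibration.** The imaging chain's real noise statistics are not
published, so the default `noise_sd` was calibrated once, by design, so that
default-configuration recovery degrades to the same order as the published
phantom accuracy (0.23 mm) while staying within it: `noise_sd = 10000` on
the 16-bit scale (roughly the bone–background contrast), fixed thereafter.
With large windows the weighted ZNCC averages noise very effectively, so
errors remain sub-pixel even at this heavy noise level.

**What the phantom does not emulate:** anatomy realism, scatter and beam
hardening, interfractional change (bowel gas), rotations, detector
nonuniformity, and capture-chain resampling. Passing the synthetic
experiment therefore demonstrates the correctness and numerical behaviour of
the pipeline under rigid translation with noise and masking — not clinical
robustness to deformation, which the method itself does not model.

## Numerical choices and degenerate inputs

* Undefined correlations are `NA` sentinels, never clamped values; a surface
  that is `NA` everywhere raises a distinct matching error.
* Argmax ties break toward the smallest offset norm, then row-major order.
* The fractional refinement grid always contains the integer peak, so the
  refined correlation can never fall below the integer-grid peak.
* Images smaller than 3×3 are rejected by the Sobel step; an overlay mask
  covering the whole image is rejected (nothing to interpolate from).
* Rows/columns with no supra-threshold edge contribute no blocked pixels: a
  fully open side is treated as usable.
* The matcher itself uses no random numbers and is bit-reproducible.

## Problem sizes used by the test suite

The module tests run on compact scenes (32–128 px images, search radius
6–12 px) where brute-force oracles — a literal term-by-term transcription of
the weighted correlation, exhaustive fractional-grid maximization, and the
error equations re-evaluated directly — are affordable; the accuracy
experiment runs once at the full default geometry (480 px, `M = 40`, all 10
pattern positions plus origin, 22 registrations). The oracle-equivalence
check uses a 0.25 px grid on 32×32 images, matching the refinement pitch it
verifies against.

## Known limitations

Translation-only (no rotation or 2D–3D registration); single-resolution
exhaustive search (no pyramids); the collimator scan's framed-field
assumption above; accuracy on the lateral view is intrinsically poorer at
low contrast, as the published experiment also observed.
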