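---
title: "Slice-based rod-cell geometry and steady-state size laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-based rod-cell geometry and steady-state size laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodsize)
```

# The geometric model

A rod-shaped cell imaged in its mid-plane is represented by a closed 2D
contour in micrometres. The package assumes the cell is a solid of
revolution *per segment*: the contour is cut into N slabs perpendicular
to the long axis, and each slab of height d = L/N is treated as a
cylinder whose diameter is the local contour width wᵢ. The per-cell
quantities are then

- length L: the span of the contour's projections onto the long axis;
- width w = (1/N) Σ wᵢ;
- volume V = Σ (π/4) d wᵢ²;
- surface S = Σ π d wᵢ;
- ratio S/V.

Two modelling decisions deserve emphasis.

**The surface formula is the stacked-cylinder lateral area.** It omits
the slant factor √(1 + (w′/2)²) of a true surface of revolution, so it
underestimates strongly curved regions (about 21% on a hemispherical
cap). This is deliberate: it is the quantity the slicing procedure
defines, and all surface results in the package use it. The
slant-corrected frustum sum is available as a separate diagnostic
(`surface_revolution()`, reported as `surface_slant` by
`quantify_cell()`) and enters no primary output.

**Length is the axis-projection span.** For a straight cell this equals
the Euclidean distance between the two extremities; for a bent cell the
two differ. Both are computed (`cell_length()` returns the tip-to-tip
distance as an attribute); the projection span is canonical because it
is the quantity the slab decomposition is built on.

## Axis estimation

The long axis is the first principal axis of the *enclosed region*,
computed from the polygon's area-weighted second central moments (the
standard polygon-moment formulas), not from the vertex scatter. This
makes the axis independent of how densely the outline is digitised: a
contour with many vertices crowded on one cap gives the same axis as a
uniformly sampled one. Degenerate inputs (zero area, collinear points)
raise explicit errors. The direction sign is fixed (positive x,
tie-broken towards positive y) so downstream coordinates are
reproducible; every output is invariant to that choice.

## Width measurement and numerical choices

The axis span [0, L] is partitioned into N equal slabs. The width of
slab i is measured where the slab's *centre line* (the perpendicular at
sᵢ = (i − ½)d) crosses the contour polygon, as the extent of the exact
edge-crossing ordinates. Centre-line evaluation makes the sums behave
like midpoint quadrature rules — errors shrink roughly as N⁻² on smooth
profiles — whereas taking the max–min extent of all points falling
*inside* each slab systematically overestimates V near the caps (about
+2% at N = 50 for a spherocylinder, measured during development), which
is why it is only the fallback.

Supporting choices:

- **Resampling.** Before slicing, the contour is resampled to uniform
  arc-length spacing with at least max(4N, 400) points, *retaining the
  original vertices* so corners are never cut. Retention is what makes
  the constant-width (rectangle) case exact to machine precision at any
  N — the terminal slab centre lines would otherwise cross corner-cut
  chords.
- **Starved slabs.** A centre line yielding fewer than two crossings can
  only occur for degenerate outlines; such slabs fall back to the extent
  of resampled vertices inside the slab, then to linear interpolation
  from the nearest resolved neighbours; terminal slabs with no
  information get width 0.
- **Defaults.** N = 50 segments, configurable. All coordinates are
  continuous micrometres; pixel-to-micrometre conversion happens at
  contour extraction and nowhere else.

The resulting guarantees, all covered by tests: rigid-motion invariance
and k/k²/k³ homogeneity to better than 10⁻⁶ relative; exactness on
constant-width cells; ≤1% error at N = 50 against quadrature limits for
spherocylinders, with monotone convergence in N.

# The synthetic-cell generator

`shape_spec()`/`make_contour()` define an analytic rod outline: a
cylindrical body of width 2r with elliptical caps (`cap_aspect` 1 =
hemispheres, 0 = flat ends), optionally modulated by a smooth width
wobble (1–3 low-order cosine modes, relative amplitude < 0.2) so shapes
deviate from perfect spherocylinders the way real cells do, and
optionally bent along a circular-arc midline. Ground truth is computed
by high-resolution trapezoid quadrature (2 × 10⁵ + 1 nodes) of the
continuum limits of the slice formulas, ∫π h² dx and ∫2π h dx for
half-width h — i.e. the truth is defined in the same geometric
convention the estimator targets, which is what makes round-trip errors
interpretable. Bent shapes define their truth along the arc-length
midline and are used only as robustness probes.

Rendering (`render_cell()`, `render_field()`) produces three channels on
a pixel-centre grid (row → y, column → x, origin top-left): an exact
scanline rasterisation of the polygon (mask), a grey background with a
smoothed dark halo at the mask edge plus Gaussian noise (brightfield
stand-in), and a marker channel with a 0.5 µm bright band perpendicular
to the axis at mid-length when the cell is septating (`septum_contrast`
times the baseline), emulating a septum-localised fluorescent stain.
The renderer is *not* an optics simulation: no point-spread function,
no z-stack, no touching cells. Passing the pipeline's tests therefore
demonstrates correctness of the geometry and statistics, not robustness
to real brightfield artefacts.

# Contour extraction and septum selection

`extract_contours()` thresholds the (optionally Gaussian-smoothed)
image — fixed level or Otsu — labels connected components, drops
objects below `min_area_um2` or touching the image border (their
geometry would be truncated), and traces each remaining component with
sub-pixel, linearly interpolated iso-contours at the threshold level.
The primary path segments the mask channel; a `polarity = "dark"` mode
(threshold inverted, ring interiors filled) handles brightfield-like
images but is intentionally simple — high-fidelity brightfield
segmentation is out of scope.

`select_septated()` replaces manual curation of dividing cells: marker
intensity averaged over a 0.5 µm band at mid-length is compared with the
median over the rest of the interior, and cells with band-to-background
ratio ≥ `septum_snr_min` (default 2) are kept. On clean synthetic
fields selection is exact; at a band contrast of 3 with pixel noise the
F1 stays above 0.95 in the shipped tests. These thresholds are not
calibrated against any real dataset.

# The simulated study design

`default_panel()` reproduces the design of a steady-state turbidostat
panel: 17 titration-arm cultures — one base minimal-medium culture plus
6 ammonium chloride doses (10–50 mg/L), 5 glucose doses (0.5–2.0 g/L)
and 5 cycloheximide doses (0.5–3.0 mg/L) — and 6 nitrogen-source /
reference cultures (ammonium reference plus five amino-acid sole
nitrogen sources). Doses map to growth rates through saturating
(Monod-like) curves for nutrients and a hyperbolic inhibition curve for
cycloheximide; only the resulting µ (0.06–0.26 /h) matters downstream.

The generative size law (`size_law_spec()`) encodes the qualitative
structure the analysis is meant to detect, with defaults chosen as
biologically plausible for fission yeast at division rather than as
estimates of any published fit:

- mean volume V(µ) = 300 µ + 30 µm³ for titration classes and base
  (≈ 108 µm³ at the base rate, ≈ 48 µm³ at the slowest titration);
- cycloheximide cultures follow their own shallow line
  (−50 µ + 121 µm³), so volume *rises* slightly as translation
  inhibition slows growth;
- nitrogen-source cultures sit 2.5× above the main line, except the
  proline-like culture and the ammonium reference, which lie on it;
- mean width per class follows w(µ) = a + bµ: steeply increasing for
  ammonium (cells thin markedly when nitrogen-starved), moderately for
  glucose, slightly decreasing for cycloheximide, flat for base and
  nitrogen sources; all rules meet near 4 µm at the base rate so the
  arms are continuous with the base culture. Through S/V ≈ 4/w these
  rules induce the class-specific surface-to-volume trends.
- per-cell volumes are lognormal with CV 0.1 (mean-preserving
  correction, so culture means are unbiased); widths vary with one
  fifth of that CV, reflecting that rod cells divide at variable length
  but nearly constant width; 50 cells per culture;
- OD regrowth series: od₀·e^{µt} sampled every 0.5 h for 3 h with 2%
  multiplicative lognormal noise.

Per-cell length and surface follow from the volume and width via
spherocylinder geometry under the slice-formula convention. With the
cell CV set to zero the whole generative chain is exact, which the
tests exploit: fits must then recover the configured slope and
intercept to 10⁻⁹.

# The statistical layer

- **Growth rate**: OLS of ln OD on time; exact on noiseless
  exponentials; R² is computed explicitly with a guard so a constant
  series reports µ = 0, R² = 1 rather than 0/0.
- **Culture summaries**: arithmetic means and SEMs per metric. The S/V
  summary is the *mean of per-cell ratios*, matching per-cell
  quantification; the ratio of means is carried as a diagnostic column
  (`sv_of_means`) only.
- **Size-law fits**: unweighted OLS over culture means, one point per
  culture (matching a one-point-per-culture presentation of such data),
  95% CIs from the t distribution; an SEM-weighted variant is available
  behind a flag. Titration fits include the base-medium culture, which
  anchors the unperturbed end of each arm.
- **Collapse**: the claim that two modulation classes share one
  volume–growth-rate line is formalised — the package's own choice, not
  an inherited procedure — as an extra-sum-of-squares F-test of a
  shared line (2 parameters) against per-class lines (4 parameters).
  When both classes are jointly collinear the residuals of both models
  are numerically zero and F is defined as 0. The test is exact-level
  under the simulator's near-normal culture means (type-I rate ≈ 0.05
  in the shipped calibration check) and has power ≈ 1 against a 2.5×
  volume offset at matched growth rates.
- **Trend classification**: per-class S/V-slope CIs; labels negative /
  positive / none by whether the CI excludes zero. Nitrogen-source
  cultures are fitted on their own (no base culture: their reference is
  the ammonium-source culture inside the class) and are expected to
  label "none".

No multiple-testing correction is applied across metrics; the fits are
descriptive.

# Problem sizes and determinism

The shipped tests and the acceptance script use: 100 random shapes for
invariance; 100 rendered cells at 0.05 and 0.025 µm/px for the
round-trip; three 20-cell fields for septum selection; 200 replicate
studies (base + 5 ammonium + 4 glucose cultures, 50 cells each) for
recovery/coverage; 200 replicates each for collapse calibration and
power; 30 replicate full panels for trend-sign recovery. These sizes
give Monte-Carlo standard errors comfortably inside the assertion
margins while keeping a full run to a few minutes. Every stochastic
step is seeded; generators are pure functions of (spec, seed), and
`with_local_seed()` keeps the caller's RNG stream untouched.

# Known limitations

- The brightfield rendering and its "dark" segmentation path are
  schematic; no claim is made about performance on real brightfield
  stacks (no PSF, no focus selection, no touching cells).
- Bent-cell ground truth is approximate (arc-length convention), and
  strong curvature combined with wobble is untested territory.
- The surface output inherits the stacked-cylinder convention; compare
  only with data produced under the same convention, or use the
  slant-corrected diagnostic.
- Septum-selection thresholds are tuned on the synthetic marker model;
  real stains with cytoplasmic background gradients may need different
  `septum_snr_min` or band width.
- The generative defaults (volume line, width rules, offsets) are
  plausible configuration, not estimates; analyses of real data should
  treat them purely as test scaffolding.
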