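---
title: "Morphometry and morphodynamics of SICM scan pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and morphodynamics of SICM scan pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicmorph)
```

## The measurement and its data model

Scanning ion conductance microscopy (SICM) in hopping mode maps the
topography of soft, living specimens without contact: at every pixel a
nanopipette approaches vertically until the ion current drops by a preset
fraction, records the z position, and retracts. Each scan line along the
fast axis (x) is acquired twice, once forward and once backward, while the
slow axis (y) advances once per line. `sicmorph` analyses such
forward/backward pairs of height maps of isolated, substrate-immobilized
organelles — primarily metabolically active mitochondria, whose apparent
heights and diameters range from roughly 0.2 to 2.8 µm.

All lengths are kept in nm internally (volumes in nm³, times since
preparation in hours); file metadata declares units and is converted on
read. Heights are treated as samples at pixel centers; rows are the slow
axis, columns the fast axis. The central S4 classes are `Topography` (one
scan direction), `ScanPair`, `MeasurementRecord` (pair plus time since
preparation `t_P`, specimen class, isolation route, completeness flag) and
`ObjectMask` (a single connected component).

## Preprocessing

The standard chain mirrors common SPM practice:

1. **Row alignment** (`alignRowsMedian`) subtracts each scanline's median;
   the variant `alignRowsMedianDiff` removes the cumulative medians of
   consecutive row differences and then re-anchors the minimum at zero
   (the row differences leave the global offset undefined).
2. **Mean-plane subtraction** (`subtractMeanPlane`): the ordinary
   least-squares plane over all non-missing pixels.
3. **Zero floor** (`zeroFloor`): the minimum becomes the substrate zero.

Two caveats are deliberate design positions. First, row alignment is
*opt-in* in the pipeline default (`defaultStudyConfig()` uses only plane
subtraction and zero floor): when the object spans the majority of a
scanline, the row median sits on the object rather than the substrate and
the "correction" carves the object apart. This is the classic failure mode
of median-based scanline correction on compact tall objects, and the
synthetic frames contain no scanline offsets to begin with. Second, the
composed chain is *not* one-step idempotent: row-median zeroing and
least-squares plane removal are individually exact projections, but they
do not commute, so a second pass moves the result slightly (on structured
test data, by under 5% of the first pass's correction). The test suite
asserts per-operation idempotence exactly and composite contractivity,
rather than a false equality. The order of operations is recorded in the
study configuration.

Missing pixels are excluded from medians and plane fits and propagate
unchanged. Segmentation (`segmentObject`) thresholds at 10% of the maximum
height, keeps the largest 8-connected component, and fills holes; with
substrate roughness of a few nm against objects of hundreds of nm, the
result is insensitive to the threshold, which remains configurable.

## Shape metrics

**Outline.** The object outline is the sub-pixel iso-contour of the height
field at a fraction (default 0.10) of the object's maximum height,
extracted by marching squares with linear interpolation
(`grDevices::contourLines`). Pixel-edge perimeters are biased high by up
to 4/π; the interpolated contour removes this bias, which matters because
the roundness statistic is a perimeter ratio.

**Roundness and classification.** `roundness()` computes
R = p_m / (2√(πA)): the outline perimeter against the perimeter of the
equal-area circle. R = 1 is a circular projection; deviations of at most
15% (inclusive) classify as spherical/ellipsoidal, larger ones as
irregular. The boundary comparison carries a few-ulp epsilon so that
values like R = 0.85 stay inside the inclusive boundary under binary
floating point.

**Volume and surface area.** V = ΔxΔy Σ z over the mask;
SA is triangulated: each grid cell is split along a fixed diagonal into
two 3-D triangles over the four corner samples, summed over cells with at
least one corner in the mask. Including boundary cells counts the steep
side walls; the inaccessible bottom face is never added. The alternative
diagonal changes SA by well under 1% at the default pitches. On a
discretized hemisphere (r = 500 nm, 5 nm pitch) the implementation is
within 0.9% of 2πr² and within 0.01% of (2/3)πr³, converging as the pitch
shrinks; the test suite fixes these checks at 1.5% and 1%.

**MCI\*.** The modified mitochondrial complexity index
MCI\* = SA^{3/2} / (6√π·V) is normalized to 1 for a full sphere and is
invariant under uniform scaling. Because the probe sees only the top
surface, the smallest value a substrate-bounded height field can attain is
that of a hemisphere top, 1/√2; only the evolution of MCI\* over repeated
measurements is interpreted, via a one-sided one-sample t-test on the
(last − first) differences at the 90% confidence level
(`mciDecreaseTest`).

**Diameters.** Because the choice of diameter definition for regular
shapes is ambiguous, both the slow-axis extent `d_slow` (the headline
value for irregular shapes) and the equal-area circle diameter
`d_circle_equiv` are reported; `d_sphere_equiv` = (6V/π)^{1/3} is the
size measure used for grouping.

## Morphodynamics: difference images and TEV

The difference image is the pixelwise backward-minus-forward map (positive
= backward higher). The total edge volume

TEV = Δx·Δy·Σᵢ |zᵢ^bwd − zᵢ^fwd|

is computed over the full preprocessed frame, not only the mask, because
edge bands extend partially outside the object footprint. TEV is
non-negative, symmetric under swapping scan roles, linear in the pixel
area, additive over disjoint pixel sets, and equal to ΔxΔy times the L1
norm of the difference image — all covered by oracle tests.

The time trend is an unweighted ordinary least-squares line
TEV = intercept + slope·t_P (`tevTrend`), with the zero crossing
t_zero = −intercept/slope reported only for negative slopes, alongside a
one-sided regression p-value for the decaying alternative. Two exclusions
are applied by default and are configurable: partial captures (the flag
marks records that caught more than 90% but less than 100% of the object,
whose TEV is nominally underestimated) and the submitochondrial-particle
group. Grouping uses `d_sphere_equiv` with a 1000 nm cutoff (half-open:
the cutoff itself is a mitochondrion), chosen between the two modes of the
bimodal size distribution (below 1.0 µm versus above 1.5 µm).

Even for identical geometry, two σ-noisy scans produce a TEV floor of
ΔxΔy·N·2σ/√π (folded Gaussian of the difference); at the default study
conditions this is about 1.7×10⁷ nm³, an order of magnitude below the
edge-memory TEV of a fresh preparation, and it shifts the extrapolated
zero crossing upward by a fraction of an hour. The trend deliberately does
not subtract this floor — the measured statistic is reported as defined.

## Height intermittency

At steep edges, weakly immobilized cap-shaped objects can transiently
escape the probe ("tilting"), so single fast-axis lines drop abruptly to
near-substrate height and recover. `detectDropouts` formalizes an event as
a maximal run of columns below `fLow`·z_max flanked on both sides, within
the search window, by columns at or above `fHigh`·z_max. The defaults
fLow = 0.2 and fHigh = 0.5 map "nearly substrate height" to below 20% of
the object height; both are relative, so detection is invariant under
height rescaling, and both are exposed in the configuration.
`intermittencySummary` scans every mask row in both directions and extends
the window 500 nm beyond the mask span, since events also occur several
hundred nm away from the object's edge. Events are counted per direction;
whether an event "spans" both directions is not well defined by the
phenomenon, so no cross-direction merging is attempted.

## The synthetic generator

`simulateStudy` provides ground truth for every stage. It emulates:

* **Shapes**: spherical caps z(ρ) = √(r² − ρ²) − (r − h), ellipsoidal
  variants (x semi-axis scaled), and irregular unions of displaced caps
  glued by a central lobe so the footprint stays one connected component.
  Sizes are drawn from a two-component mixture mirroring the bimodal
  distribution: a small mode near 460 nm equivalent diameter
  (submitochondrial particles) and a large mode near 1.6 µm.
* **Undulations**: a band-limited Gaussian random field (correlation
  length 100 nm) added on the object only. The "≈100 nm" amplitude is read
  as peak-to-peak, so the field is scaled to RMS = amplitude/2 *after*
  being tapered by tanh(z/amplitude) toward the rim; the taper keeps the
  footprint boundary from being pushed below the substrate.
* **Edge memory**: the backward scan's footprint boundary is displaced
  laterally (a per-angle radial rescale about the footprint centroid) by
  δ(θ) = δ(t_P)·(1 + a·cos(θ − φ) + smooth seeded perturbation), with
  δ(t_P) = δ₀·max(0, 1 − t_P/t_zero). Modeling the effect as a lateral
  boundary displacement (not a height change) reproduces the ± edge bands
  seen in difference images; the linear decay reproduces the measured
  trend, with defaults δ₀ = 100 nm and t_zero = 18.8 h. The displacement
  magnitude jitters by 10% between records. Small-mode records get δ₀ = 0:
  submitochondrial particles show no edge memory, so their TEV is purely
  instrumental and time-independent.
* **Dropouts**: pixels on the steep upper shoulder (fast-axis slope above
  1, height ≥ 65% of the scan maximum) start a run with probability
  q = 0.1, continuing over eligible pixels up to 3 px; dropped pixels fall
  to substrate level. Restricting eligibility to the upper shoulder makes
  every injected event a flanked event in the detector's sense, which is
  what makes a precision/recall benchmark well defined.
* **Noise**: i.i.d. Gaussian z-noise, σ = 1 nm (the instrument's
  z-resolution). Grid default 128×128 at 30 nm pitch (a 3.8 µm frame that
  accommodates the largest displaced irregular objects).

All randomness flows from named seeds; regeneration is bit-reproducible,
and the ground-truth ledger records shape parameters, realized δ(t_P),
dropout pixels and (for spherical caps) the closed-form V = πh²(3r − h)/3
and SA = 2πrh, which the analysis side must recover on the noiseless
grids — closing the loop between generator and analyzer.

What the generator does **not** emulate: membrane protein signatures
(absent in the real topographies, obscured by membrane fluctuations),
pipette current/feedback dynamics, drift beyond the modeled effects,
tip–sample convolution, and any mechanistic model of *why* the edge
responds (the electrostatic hypothesis is outside the computational
scope). Passing tests therefore validate the statistical machinery under
the stated structure, not the biology of real scans.

## Benchmarks the tests pin down

Problem sizes are chosen so the full suite runs in well under a minute per
file: hemisphere convergence uses r = 500 nm at 5 nm pitch; TEV oracles
use 100 random 16×16 pairs; the trend-recovery benchmark simulates 20
studies of n = 30 records at 128×128, with t_zero = 18 h and 10% magnitude
jitter, and requires the fitted t_zero within 10% in at least 90% of
studies (dropouts are disabled there — intermittency is a separate
phenomenon with its own precision/recall ≥ 0.9 benchmark, and its
full-height difference spikes would otherwise contaminate a benchmark of
the edge-memory trend); the null arm (δ₀ = 0) must show no significantly
negative slope in at least 90% of studies. Isoperimetric floors
(R ≥ 0.98, MCI\* ≥ 1/√2 − 0.03 for substrate-bounded objects) are asserted
for every segmented object of a default 12-record study.

The measured-data headline values (the 18.8 h zero crossing and the
1644 ± 88 nm vs 460 ± 33 nm group means) require the deposited raw scans
and are not reproduced at desk scale; the deposited data can be run
through `runPipeline` via a manifest as an external benchmark, recording
the inclusion choices (partial captures, grouping cutoff) alongside.

## Known limitations

* The radial edge-memory warp assumes star-shaped footprints; extremely
  concave objects would need a boundary-normal displacement field.
* The contour-based area/perimeter require the object not to touch the
  frame border; clipped objects are flagged (`border_clipped`) rather than
  silently measured.
* Segmentation assumes a single dominant object per frame.
* The TEV noise floor is reported, not subtracted; comparisons across
  instruments with different noise or pixel counts should account for it.
* Welch comparisons and the MCI\* test report raw p-values; no
  multiple-testing correction is applied, and no significance stars are
  printed — exact p-values are unambiguous where star conventions are
  not.
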