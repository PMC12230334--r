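# sicmorph

Morphometry and morphodynamics of scanning ion conductance microscopy
(SICM) topographies of isolated organelles.

Hopping-mode SICM images soft, living specimens — here isolated,
substrate-immobilized mitochondria — without contact, recording every scan
line twice (forward and backward along the fast axis). `sicmorph` turns
such forward/backward height-map pairs into quantitative morphology and
viability statistics:

* **Preprocessing** — scanline alignment by row medians or by medians of
  row differences, least-squares mean-plane levelling, zero-floor, and
  threshold segmentation of the dominant object.
* **Shape metrics** — projected roundness R = p_m / (2√(πA)) from a
  sub-pixel iso-contour outline, with the inclusive 15% classification
  into spherical/ellipsoidal vs irregular; volume V = ΔxΔy Σz; surface
  area by cell-wise triangulation; the modified mitochondrial complexity
  index MCI\* = SA^{3/2}/(6√π·V), normalized to 1 for a sphere (a
  hemispherical top surface, the flattest substrate-bounded cap, gives
  1/√2); slow-axis, equal-area-circle and equivalent-sphere diameters.
* **Morphodynamics** — difference images (backward − forward), the total
  edge volume TEV = ΔxΔy Σ|z^bwd − z^fwd|, its linear decay with time
  since preparation t_P and the extrapolated zero crossing
  t_zero = −intercept/slope, equivalent-diameter grouping of
  mitochondria vs submitochondrial particles, a one-sided t-test for
  MCI\* decrease over repeated measurements, and Welch group comparisons.
* **Height intermittency** — detection of abrupt dropout events (height
  falling to near-substrate level between high flanks) along fast-axis
  line profiles, per scan direction.
* **Synthetic studies** — a fully seeded generator of cap-shaped objects
  with ~100 nm undulations, a linearly decaying, angularly asymmetric
  forward/backward edge displacement, stochastic edge dropouts and 1 nm
  z-noise, with a ground-truth ledger for benchmarking every stage.

Height maps are read and written as annotated ASCII matrices, bare CSV
matrices, or 32-bit float TIFF with JSON sidecars; studies are described
by a manifest CSV.

## Worked example

```r
library(sicmorph)

study <- simulateStudy(n = 8, masterSeed = 42,
                       base = synthConfig(dropoutProb = 0))
rec <- study$records[["active-004"]]
rec
#> MeasurementRecord 'active-004': active_mito (none isolation),
#> t_P = 10.03 h, 128 x 128 px [partial capture]

fwd <- preprocessTopography(forwardScan(rec@pair))
rep <- shapeReport(fwd, segmentObject(fwd))
signif(rep[, c("roundness_R", "volume_V_nm3", "mci_star",
               "d_sphere_equiv_nm", "h_max_nm")], 4)
#>   roundness_R volume_V_nm3 mci_star d_sphere_equiv_nm h_max_nm
#> 1       1.023    1.618e+09    0.755              1457    998.9
rep$shape_class
#> [1] "spherical_ellipsoidal"
totalEdgeVolume(rec@pair)
#> [1] 191300000
```

The outline is within 2.3% of a circle (well inside the inclusive 15%
band, hence "spherical_ellipsoidal"); the ~1.6×10⁹ nm³ volume corresponds
to a 1.46 µm equivalent-sphere diameter — a mitochondrion, not a
submitochondrial particle; MCI\* = 0.755 sits just above the hemispherical
floor 1/√2 ≈ 0.707, i.e. a nearly dome-shaped object; and the TEV of
1.9×10⁸ nm³ reflects the edge displacement at t_P ≈ 10 h.

A full study, including the TEV-vs-t_P trend:

```r
bundle <- runPipeline(list(
  input = list(simulate = list(preset = "active", n = 30,
                               base = list(tZero = 18.8, dropoutProb = 0))),
  seed = 42))
bundle$trend
#> TrendFit: TEV = 5.703e+08 -3.321e+07 * t_P (nm^3, t_P in h),
#>           R^2 = 0.607, n = 23
#>   zero crossing at t_P = 17.2 h
```

The fit excludes partial captures and the submitochondrial group by
default (both toggles in the config) and recovers the configured 18.8 h
decay within the expected stochastic scatter. `runPipeline()` also writes
shape reports, TEV tables, intermittency events, Welch comparisons and
the trend as CSV/JSON when `outDir` is set; a thin command-line wrapper
with `simulate`/`metrics`/`tev`/`trend`/`profile`/`intermittency`/`report`
subcommands lives in `inst/scripts/sicmorph-cli.R`.

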