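---
title: "Methods: quantitative transiliac bone-section analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative transiliac bone-section analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosect)
```

# Scope

`osteosect` implements the standard quantitative workup of a transiliac bone
biopsy cross-section — two cortical plates flanking a trabecular compartment —
from two imaging modalities:

1. a **quantitative backscattered electron image** (qBEI), from which the
   mineralization density distribution (BMDD) and the structural indices are
   measured, and
2. a **Goldner-style phase map** of the stained section, from which osteoid,
   cell-surface and marrow-adiposity indices are measured.

Because clinical specimen images are not freely available, the package ships a
seeded synthetic-section generator that produces paired images, label maps and
noiseless ground truth, so every stage of the pipeline can be validated
end to end.

# The calibration model

qBEI gray levels grow monotonically with the mean atomic number $\bar Z$ of
the target. The package models the detector signal as *linear* in $\bar Z$ and
anchors the scale with two pure standards imaged in the same frame:

* carbon ($Z = 6$) defines 0 wt% Ca;
* aluminum ($Z = 13$) defines
  $\mathrm{Ca}_{\mathrm{Al}} = 39.86\,\frac{13-6}{\bar Z_{\mathrm{HA}}-6}
  \approx 34.58$ wt% Ca,

where $\bar Z_{\mathrm{HA}} = 14.068$ is the mass-fraction-weighted mean
atomic number of hydroxyapatite, computed once from standard atomic weights,
and 39.86 wt% is the calcium content of stoichiometric hydroxyapatite — the
physical saturation of the scale. Both constants are explicit and overridable
(`calibration_standards()`), since an instrument-specific convention may
differ. Gray levels below the carbon anchor (detector noise) clamp to 0 wt%
and stay valid; levels that would exceed hydroxyapatite are flagged invalid.
Detector linearity is assumed; no beam-drift correction is attempted.

## Round-trip exactness and the quantized truth

The simulator synthesizes the gray image by *inverting the same two-anchor
linear model*, which makes the calibration testable: fitting from the embedded
patches and applying the curve must reproduce the ground truth exactly on
noiseless images. Since a real image holds integer gray levels, the noiseless
ground-truth calcium map is defined **on the quantized gray grid**: sampled
calcium values are mapped to gray, rounded, and mapped back. The quantization
step (≈ 0.0009 wt% Ca with the default anchors 5000/45000 on a 16-bit scale)
is far below any biological scale, and the round trip is then exact to machine
precision — which the acceptance suite asserts with `expect_identical()`.

# The BMDD and its five parameters

The BMDD is the area-fraction histogram of calcium weight percent over
mineralized bone. Choices that matter:

* **Mineralized threshold** `t0 = 5.2` wt% Ca separates mineralized matrix
  from osteoid/marrow; the clinical sources do not print their cut, so it is a
  documented, configurable default sitting far from both populations.
* **Bin width** `0.17` wt% Ca, the conventional qBEI granularity
  (approximately one 8-bit gray level); binning happens *after* per-pixel
  calibration, never on raw gray levels, so gray and calcium bins cannot
  alias. The bin grid is anchored at 0 wt% Ca. Note `17.68/0.17 = 104`
  exactly: the CaLow threshold falls on a bin edge of the default grid.
* **CaMean** is the area-weighted mean of bin centers; **CaLow/CaHigh** are
  the area shares below 17.68 / above 25.30 wt% Ca (the 5th/95th percentiles
  of the adult trabecular reference BMDD) with the straddling bin apportioned
  by linear interpolation, which removes bin-width sensitivity.
* **CaPeak** is the argmax after an optional (default-on) 3-bin moving
  average. Ties resolve first to the highest raw bin — so an isolated spike
  keeps its own bin despite the smoothing plateau — then to the lowest bin
  center, making the peak deterministic.
* **CaWidth** is the full width at half maximum of the *raw* histogram by
  linear interpolation between bin centers, measured at the crossings nearest
  the global peak (the dominant mode of a multimodal BMDD). A single occupied
  bin therefore has CaWidth equal to one bin width.
* **Cortical summary**: the arithmetic mean of the two cortices' parameters,
  or the single cortex when only one is available; an empty compartment is
  reported `"not evaluable"`, not an error.

Two numerical caveats are worth stating because tests rely on them. First,
*shift equivariance* (adding δ to every pixel shifts CaMean and CaPeak by
exactly δ) holds exactly only when δ is a multiple of the bin width, because
the grid is fixed; for incommensurate δ the discrepancy is bounded by the
discretization. Second, the *half-bin agreement* between the binned CaPeak and
an exhaustive (histogram-free) mode estimate is a statement about
discretization error, not about sampling noise: for smooth distributions at
10^5–10^6 pixels both estimators jitter by about one bin, so the property is
verified on sharp (zero-variance) mixture components, where mode estimation is
exact, while CaMean, CaLow and CaHigh — plain sample statistics — are verified
on smooth sections too.

# Histomorphometry

Surfaces are one-pixel-wide boundary sets. Two conventions:

* **Open ROI edges.** A neighbour outside the region of interest (or the
  image) creates no surface: a trabecula truncated by the field edge is not
  given an artificial boundary there. Consequently a *fully* mineralized ROI
  has zero perimeter; it reports BV/TV = 100% with undefined Tb.Th rather
  than an error.
* **Perimeter with diagonal correction.** Boundary length uses the weighted
  border-pixel scheme popularised by scikit-image (weights 1, √2, (1+√2)/2 by
  neighbour configuration); naive edge counting overestimates oblique
  boundaries by up to ~27%. Ratio indices (OS/BS, Ob.S/BS, …) use boundary
  *pixel counts*, where the estimator bias cancels.

Indices: BV/TV is exact pixel counting; Tb.Th = 2·area/perimeter under the 2D
plate model, so Tb.N = (BV/TV)/Tb.Th holds to machine precision *by
construction* (a distance-transform alternative is available via
`tb_th_method = "dt"` as a cross-check); Ct.Wd is twice the mean
distance-transform ridge value along the cortical medial axis, robust to the
irregular, trabecularized cortices seen in disease — with the image border
treated as background so a plate cut by the field edge is measured two-sided.
Ct.Wd is reported in **mm**: the clinical reference table prints "Cortical
width [µm]" with values around 0.3–1.1, which is inconsistent with micrometers
for an iliac cortex; the package flags rather than rescales this discrepancy.

Pixels are 0-based row-major where coordinates surface in the API; a pixel is
bone iff its label is mineralized (no partial-volume handling).

# Marrow adiposity

The clinical procedure is "semiautomatic"; here it is fully automatic with
explicit parameters: candidate regions are 8-connected components of the
adipocyte phase (or of bright thresholded regions in a grayscale field),
filtered by minimum area (default 525 µm², the conventional clinical cut) and
minimum circularity 4πA/P² (default 0.4 — admits roundish cells, rejects
inter-trabecular slivers). Manual curation is emulated by optional
include/exclude region-id overrides. Regions touching the field border are
retained by default (configurable). Fields are pooled by areas —
100·ΣA_adip/ΣA_marrow — as the headline value; the unweighted mean of
per-field fractions is also reported, since the sources do not state which
convention was used (with equal field areas they coincide).

# The synthetic-section generator

The generator states a world and sticks to it; it is test scaffolding, not
electron–matter physics. Defaults emulate an infant transiliac biopsy at the
published pediatric reference values:

| parameter | default | why |
|---|---|---|
| pixel size | 1.8 µm | conventional qBEI overview resolution |
| target BV/TV | 17.7% | pediatric reference mean |
| trabecular thickness | 101 µm | pediatric reference mean |
| cortical width | 300 µm per plate | infant scale (control ≈ 0.30 mm) |
| osteoid seam / coverage | 5.8 µm / 34% | reference O.Th and OS/BS |
| mixture | lamellar N(23.4, 1.55²) w=0.85; woven N(20.3, 2.0²) w=0.15 | dominant mode at the reference CaPeak, σ = CaWidth/2.355; a minor lower-mineralized mode |
| surface coverage | Ob 8.5%, Oc 1.1%, eroded 14.8% | reference surface indices |
| adipocytes | 50 cells, 600–1800 µm² | above the 525 µm² cut; axis ratio 0.6–1 ("roundish") |
| noise | σ = 350 gray ≈ 0.30 wt% Ca | plausible detector noise, zero-mean Gaussian, clipped to bit range |

Geometry: two wavy cortical plates; trabeculae as randomly oriented
stadium-shaped strips added until the target BV/TV is exceeded and then
trimmed by iterative erosion/dilation (accepting a step only if it improves
the match — realized BV/TV lands within well under 3 points of target);
osteoid seams and surface annotations stamped on randomly chosen boundary
arcs (anchor pixels plus nearest-fraction selection); adipocytes
rejection-sampled ellipses in marrow without overlap; two calibration patches
stamped in a marrow margin strip at the declared gray means. Label codes:
0 marrow, 1 mineralized bone, 2 osteoid, 3 adipocyte, 4 mineralized cartilage
(the optional high-mineralized residual-cartilage mode seen in healthy infant
trabecular BMDD), 5 calibration standard.

What the generator does **not** emulate — hence what a green test does not
establish: osteocyte lacunae (described only qualitatively in the sources),
partial-volume effects at surfaces, spatially correlated mineralization
(values are i.i.d. given the phase), detector nonlinearity or drift, Goldner
RGB color (phases are label-coded), and any 3D structure. Recovery tests
validate the measurement chain, not biological realism.

# Reporting

Reference ranges are bundled verbatim as a versioned CSV (structural, osteoid
and surface indices from older children, ages 1.5–6.9 years; BMDD from
healthy children, n = 50). `compare_to_reference()` returns a z-score and a
position against center ± 2 SD for mean±SD references, or a position against
the interquartile range for median[IQR] references; "reduced by around X%"
statements are computed as 100·(1 − measured/center) and *reported, never
asserted*. The age mismatch of the references for an infant sample is flagged
in the report metadata, not adjusted for. Report values are rounded to 2
decimals (the precision of the clinical tables), so the JSON report
round-trips exactly.

All randomness flows from one top-level seed; the demo pipeline re-run under
the same seed produces a byte-identical JSON report.

# Worked example

```{r example, eval = FALSE}
library(osteosect)
rep <- run_pipeline(demo_config(seed = 1), out_dir = "out")
rep$rows[rep$rows$group == "structural", c("parameter", "value", "z_score", "position")]
```

# Known limitations

* The PGM raster format replaces TIFF (no TIFF library in the supported
  dependency set); PGM is lossless for 8/16-bit grayscale and universally
  readable.
* Surface annotations are in-memory pixel-index sets; they are saved to
  `truth.json` by `write_section()` but the file-based pipeline rebuilds the
  phase map without them, so surface indices from files are 0 rather than
  recovered.
* The perimeter estimator is exact for isothetic boundaries and approximate
  for oblique ones; absolute Tb.Th on strongly oblique structures inherits
  that bias (ratios do not).
* CaPeak on smooth, flat-topped BMDDs is intrinsically noisy at ±1 bin; the
  3-bin smoothing reduces but cannot remove this.
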