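---
title: "Methods: DNA-content cell-cycle profiling and robust dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-content cell-cycle profiling and robust dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscycle)
```

## The problem

Cell-viability screens usually report a bulk well readout — ATP-dependent
luminescence, MTS formazan absorbance, or total DNA fluorescence — as a proxy
for the number of live cells. These proxies conflate cell number with
per-cell physiology: a cytostatic drug that arrests cells in G2 doubles or
quadruples cell size, mitochondrial mass and ATP content per cell, so the
bulk ATP signal falls far less than the cell count does. The result is
systematically underestimated potency (right-shifted EC50) or efficacy
(shallow Emax), and for biphasic compounds, non-monotonic proxy curves that
cannot be fitted at all. `hcscycle` implements the image-based alternative —
count nuclei directly, classify each cell's position in the cell cycle from
its integrated DNA-stain intensity, and quantify per-cell mitochondrial mass
— together with the robust curve-fitting and assay-comparison machinery
needed to diagnose such discrepancies, and a synthetic data generator that
makes every stage testable against ground truth.

## DNA-content normalization and five-bin classification

Integrated per-nucleus DNA intensity is proportional to DNA content, but the
absolute scale drifts between experiments, plates and wells. The pipeline
anchors the scale on the diploid (2N) peak of the vehicle-control
population:

1. **Reference estimation** (`estimate_reference()`). Pooled control-well
   intensities are log2-transformed and smoothed with a Gaussian kernel
   density (bandwidth 0.04 log2 units, evaluated on a 0.005-unit grid —
   stable for the ~6% CV broadening typical of image-derived histograms).
   The 2N anchor is the *lower-intensity major mode*: among modes reaching
   at least half the maximum density, the lowest is taken, so a tall 4N
   (G2/M) peak one log2 unit above is never mistaken for 2N. A near-equal
   competitor about one log2 unit higher triggers a warning. At least 200
   pooled control cells are required.
2. **Per-well normalization** (`normalize_well()`). Each well's own 2N peak
   is sought within ±0.3 log2 units of the reference (this half-width is a
   package default; it absorbs ordinary staining drift while keeping the 4N
   peak of a normal well out of the window). Intensities are rescaled so
   that the per-well peak maps to normalized DNA content 1; a true 4N
   population then sits at 2, 8N at 4. If no credible in-window mode exists
   — a fully arrested 4N well has none — the pooled reference is used and
   the well flagged. A candidate peak must be an interior local maximum with
   at least 10% of the well's maximum density, which distinguishes a real
   residual 2N population from the rising tail of a 4N peak.
3. **Classification** (`classify_cells()`). Cells are binned on the
   normalized linear scale: sub-G1 below 0.75, 2N in [0.75, 1.25), S in
   [1.25, 1.75), 4N in [1.75, 2.5), >4N at and above 2.5. The printed
   thresholds overlap at their endpoints; we resolve them as half-open,
   lower-inclusive intervals so classification is deterministic and
   order-free. The thresholds are interpreted on the *linear* normalized
   scale (2N = 1, 4N = 2), the only reading consistent with anchoring 4N at
   twice the 2N value; the alternative convention — the same numbers applied
   to `1 + log2(content)` — is available via `scale = "log2"`. Wells with
   fewer than 50 cells still report fractions but are flagged unreliable.

Because both the reference and the per-well peak move with any global
intensity rescaling, normalized values and bin fractions are exactly
scale-invariant — a property the test suite checks directly.

## Robust constrained 4PL dose-response fitting

`fit_4pl()` fits the decreasing four-parameter logistic
$$y = \mathrm{bottom} + \frac{\mathrm{span}}{1 + 10^{\,h\,(x - \log EC_{50})}}$$
to percent-of-control responses ($x$ = log10 molar concentration), returning
a classed model object with the usual `print`, `summary`, `coef`, `predict`,
`plot` and `residuals` methods. Emax — the maximal percent signal reduction —
is `100 − bottom`, and `log10(EC90) = logEC50 + log10(9)/h`.

Three design elements matter:

* **Constraints.** The span is confined to (20, 100) percent and the Hill
  slope to (0.5, 4), enforced by logistic box reparameterization so the
  optimizer works on an unconstrained scale. The top asymptote is free (not
  pinned at 100): only the span is constrained. `log EC50` is additionally
  boxed to the tested range ±2 log units to keep flat series from running
  away; such series are rejected by the validity gate instead.
* **Robust loss.** Residuals are weighted by the redescending Tukey
  biweight with tuning constant 4.685 times the robust residual scale
  (normalized median absolute deviation), re-estimated each iteration, so a
  handful of aberrant wells cannot drag the curve. The optimization is
  multi-start — `log EC50` every 0.5 log unit across the tested range,
  crossed with Hill slopes 1 and 2, each start's asymptotes profiled by a
  small Tukey-IRLS linear regression (the model is linear in bottom and span
  at fixed EC50 and Hill). Candidates are screened with a few IRLS rounds,
  the best basins polished to convergence, and a final MM-style stage
  re-descends the fixed-scale objective from every polished basin. A
  weighted Gauss-Newton polish on the inlier set sharpens near-exact fits to
  machine precision. Ties are broken toward the smaller Hill slope, then the
  smaller |log EC50|. The procedure is fully deterministic.
* **Validity gating** (`assess_validity()`). A fit is accepted when its
  robust residual RMSE is below 1.5 times the global standard deviation and
  the standard error of log EC50 (from the robust-weighted linearized
  covariance) is below 1 log unit. We define the residual statistic as
  `sqrt(sum(w r^2) / (sum(w) − 4))` — a weighted residual root-mean-square
  with the final biweight weights, the only definition whose units match a
  standard deviation of percent responses — and the *global standard
  deviation* as the standard deviation of normalized responses across the
  experiment's vehicle-control wells, the natural plate-noise scale
  computable from any dataset. Flat or truncated series fail the gate
  through an unbounded `SE(logEC50)` rather than through an ad hoc rule.

Non-monotonic (rebounding) proxy-assay series — which the 4PL cannot and
should not fit — are detected separately (`detect_nonmonotonic()`): once the
replicate-mean response has fallen below `100 − 2·SD`, any later rise of more
than `2·SD` above the running minimum raises a flag, and a peak/valley split
with the same hysteresis reports the monotone segments. Biphasic double-Hill
fitting is deliberately out of scope.

## Assay-format comparison

`normalize_plate()` follows instrument conventions: ATP luminescence is
normalized to percent of the plate-averaged vehicle control without blank
subtraction; MTS absorbance and DNA-dye fluorescence first subtract the
medium-only blank mean. `ratio_curve()` reports the fold change of the
signal-to-count ratio per concentration (replicate means; concentrations
with counts below 1% of control are dropped as undefined).
`total_mito_mass()` multiplies the per-well cell count by the mean per-cell
mitochondrial intensity (fold of control) and renormalizes — a derived
dose-response series that tracks the ATP readout when ATP scales with cell
size and mitochondrial density. `compare_formats()` applies the standard
reporting rules: flag a proxy readout whose log EC50 differs from the count
fit by more than 1 log unit or whose Emax differs by more than 25 points;
censored entries (e.g. an EC50 beyond the highest tested concentration) are
represented as bounds and compared at the bound, which is conservative
because censoring always points away from agreement. An invalid proxy fit
against a valid count fit raises both flags.

## The synthetic plate simulator

`simulate_dose_plate()` generates full 384-well dose-response plates with
per-cell and per-well ground truth. Its building blocks:

* **Phenotype states** carry DNA content (G1 = 1, S uniform on (1, 2) — the
  simplest model consistent with a continuous inter-peak region; G2/M = 2;
  endoreduplicated cells 4 or 8, default 8N-dominant; sub-G1 uniform on
  (0.2, 0.75)), a cell-size multiplier, and per-area mitochondrial, ATP and
  MTS coefficients. Staining and area noise are multiplicative lognormal
  with mean exactly one, so expectations are noise-free and zero-CV draws
  are exact.
* **The untreated mixture** defaults to 60% G1 / 15% S / 22% G2/M / 3%
  sub-G1 — a plausible asynchronously cycling adherent-line profile
  (G1-dominant, small apoptotic background); no published numeric profile
  exists for this choice, so it is configurable. Sub-G1 cells retain 40% of
  G1 area, which makes bulk ATP decline as apoptosis accumulates.
* **Compound models** move the population from the untreated mixture to a
  primary phenotype along a Hill response, and optionally onwards to a
  secondary phenotype (with partial kill) at strictly higher concentration.
  Interpolation is linear in Hill-response space, giving smooth biphasic
  transitions. Final counts follow exponential growth (default ~2.4
  doublings in 48 h) inhibited by the primary Hill response, whose maximal
  inhibition sets the count-curve Emax, Poisson-sampled per well.
* **Bulk readouts** are computed from the realized cells: ATP and MTS sum
  `area × coefficient` over *all* cells (dead cells still carry residual
  signal through their shrunken area); the DNA-dye signal sums DNA content
  over non-sub-G1 cells only, emulating the membrane-impermeable quencher
  that restricts the dye to intact cells. This asymmetry is what makes the
  DNA-dye readout track counts much more closely than ATP/MTS.
* **Determinism.** Every random draw flows from one integer seed through
  counter-based per-well substreams, so results are bit-identical under a
  fixed seed and independent of well evaluation order.

Prebuilt scenarios (`hcs_scenario()`) encode the canonical discrepancy
mechanisms. Two calibrations are pinned to the reported phenomenology of
their drug classes: the pure mitotic-arrest scenario uses a 2.2× cell-size
multiplier, which against the untreated population mean size of 1.1 yields
the ~2-fold ATP-per-cell plateau characteristic of taxane-type arrest; the
arrest-then-apoptosis scenario enlarges G2-arrested cells 5×, placing the
bell-shaped ATP-per-cell peak in the reported 4–5-fold range before the
apoptotic switch pulls both signals down.

What the simulator does *not* emulate: pharmacokinetics, medium exchange,
well-edge effects, mitosis-versus-G2 discrimination by nuclear morphology,
flux-analyzer (respiration) readouts, and real instrument artifacts such as
illumination gradients or focus drift. Passing tests therefore demonstrate
the correctness of the analysis pipeline under controlled, generative
conditions — not performance on real microscope data.

## Image rendering and segmentation

`render_field()` draws each nucleus (35% of cell area) and cell body as
uniform discs whose pixel sums equal the cell's true intensities, blurs with
a Gaussian PSF (sum-conserving circular boundary), adds a uniform background
and Poisson shot noise, and places cells uniformly without overlap.
`segment_nuclei()` re-detects them: Otsu thresholding on *log* intensity
(nuclei spanning 1×–8× DNA content would otherwise straddle a raw-scale
Otsu threshold), hole filling, a distance-transform watershed (tolerance
0.5 px) to split touching nuclei, and a minimum-area filter. Integrated
intensities are background-corrected (median of non-foreground pixels) and
summed over a 4-px-dilated, nearest-object-assigned region so the PSF skirt
outside the threshold mask is recovered. Blank or saturated fields return an
empty result with a warning; border-touching nuclei are kept for counting
but flagged, avoiding density-dependent count bias while letting users
exclude them. `assign_cytoplasm()` grows cell regions from nuclear seeds by
Voronoi propagation restricted to the mitochondria-channel foreground, then
trims each region at half-maximum between background and the cell's own
plateau — self-calibrating across staining brightness, and exact at the
original disc edge for a blurred uniform disc. Fragmented apoptotic nuclei
can segment as multiple sub-G1 objects; counts include them (nuclei are what
is counted), a known and documented bias.

## Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately modest sizes
that still give stable statistics: 2000–6000 cells per simulated well for
histogram work, 20-point two-fold dilution series with duplicate wells,
100 simulated series for fit benchmarking, and single 512–1024 px fields
with 100–340 cells for imaging round-trips. Peak location uses bandwidth
0.04 and grid step 0.005 in log2 units throughout; the robust scale is
floored at 10⁻⁶ percent so that exact-fit problems remain well-posed; the
fit's multi-start grid and tie-breaking rules make it reproducible without
any random number use.

## Known limitations

* The per-well 2N peak search assumes the control reference is trustworthy;
  a plate whose *controls* are arrested would anchor the scale wrongly.
* Sub-G1 quantification counts nuclear fragments as cells.
* The 4PL machinery models decreasing responses only; stimulatory responses
  are surfaced through the non-monotonicity detector, not fitted.
* Censored-bound comparisons are conservative by construction and cannot
  recover the true magnitude of a discrepancy beyond its bound.
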