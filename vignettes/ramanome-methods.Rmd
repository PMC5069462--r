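---
title: "Models and methods behind the ramanome toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ramanome toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

A ramanome is the collection of single-cell Raman spectra (SCRS) of cells
randomly sampled from an isogenic population at one time and condition.
Each spectrum reports, band by band, the cell's momentary composition of
nucleic acids, proteins, lipids and carbohydrates, so the population-level
distribution of spectra acts as a multiplex phenotype. This vignette
documents the statistical models the package implements, the assumptions of
its synthetic-spectra generator, and the design decisions taken where the
methodology left genuine freedom.

## Data model

A `Ramanome` extends `SummarizedExperiment`: bands are rows (the ascending
wavenumber grid, canonically 1581 points over 600–1800 cm⁻¹, lives in
`rowData`), cells are columns, and `colData` carries `cell_id`, `stressor`,
`dose`, `dose_unit`, `time_min`, `replicate` and `strain`. The object is
either `raw` or `preprocessed`; the preprocessed state guarantees unit-norm,
non-negative spectra on a common grid, which every analysis function
assumes. Analyses operate on the fingerprint region, 640–1800 cm⁻¹ (both
bounds closed); preprocessing itself crops to the measured 600–1800 cm⁻¹.

## Preprocessing

* **Baseline.** Cellular autofluorescence produces a smooth background.
  We estimate it by asymmetric least squares — a Whittaker smoother whose
  weights are iteratively set to `p` above and `1 − p` below the current
  baseline — with defaults λ = 1e5 (smoothness, chosen so the baseline
  bends on ~100 cm⁻¹ scales but cannot follow 6–10 cm⁻¹ bands), p = 0.001
  and 10 iterations. On peak-free smooth inputs the residual tends to zero
  with iterations; a Gaussian band of height *h* on a quadratic background
  is recovered to within 5% of *h* (tested).
* **Quality control.** SNR = (max − median) corrected intensity divided
  by a robust noise estimate — 1.4826 × MAD of the first differences,
  scaled by √2 — from the near-signal-free 1750–1800 cm⁻¹ window. First
  differences cancel residual baseline structure and the median offset
  removes the positive residual bias of the asymmetric smoother, so
  flat, signal-free scans score well below `qcMinSnr = 3` and are
  dropped and logged.
* **Normalization.** Residual negatives (at baseline-noise scale) are
  clipped to zero and each spectrum is scaled to unit Euclidean norm
  (`l2`, default; `area` offered for comparability). L2 was chosen because
  downstream Euclidean distances then order like cosine distances, i.e.
  the analysis is scale-free: the whole pipeline is invariant to per-cell
  multiplicative gain (laser power, focus), a tested property. Exact
  normalization conventions differ across instruments and vendors, which
  is why both options are exposed.

## Population statistics

**ANOSIM.** With average ranks of all pairwise distances,
`R = (r̄_between − r̄_within)/(M/2)`, `M = n(n−1)/2`; `R ∈ [−1, 1]` and
equals 1 exactly when every between-group distance outranks every
within-group distance. Significance is by label permutation,
`p = (1 + #{R_perm ≥ R_obs})/(n_perm + 1)`, default `n_perm = 999` so the
attainable floor is p = 0.001; an exact enumeration over distinct label
partitions is available for small groups. Distances default to Euclidean
on the L2-normalized fingerprint (the distance metric is otherwise a free
choice; cosine is provided).

**Band tests.** Per band, the D-value is the difference of group mean
intensities (stressed − control); two-sided Wilcoxon rank-sum p-values
(exact below a combined n of 20 and without ties, normal approximation with
tie correction otherwise) are Benjamini–Hochberg adjusted across the
fingerprint bands because ~1500 bands are tested simultaneously; the
per-band sign call is `sgn(D)` where the adjusted p is below α = 0.001,
else 0. A `--no-adjust` style option (`adjust = "none"`) reproduces
raw-p behaviour. D-values at stress onset (t = 0) are defined as zero.

**SDM.** Reproducibility across biological replicates: per band, the
sample SD of the replicate mean spectra; reported as mean ± SD over the
fingerprint bands. The replicate-mean reading of this statistic is one of
several in circulation, so it is isolated behind a single function.

**Heterogeneity.** The RSD (SD/mean across cells, per band) of a
normalized ramanome quantifies inter-cellular phenotypic heterogeneity;
bands with |mean| < 1e−6 are flagged undefined. Condition comparisons use
Kruskal–Wallis on *replicate-level* RSD values — cells within a replicate
are not independent measurements of the population's heterogeneity, so
using them as test units would pseudo-replicate. Under the simulator's
lognormal model the RSD converges to `sqrt(exp(σ²) − 1)` (tested at
N = 200 and 2000).

## Chemometrics

Random-Forest classification (the `ranger` implementation, 500 trees,
single-threaded and seeded for reproducibility) is evaluated by stratified
k-fold (default 5) or leave-one-out cross-validation; the report carries
the pooled confusion matrix, overall accuracy and per-class
sensitivity/specificity, plus impurity importances ranked with ties broken
toward the lower wavenumber. PC-LDA retains the fewest principal
components reaching 95% variance (capped to keep the LDA well-posed) and
applies Fisher LDA on the scores; per-band contributions are the PC
loadings back-projected through the discriminant weights.

PLSR uses the NIPALS PLS1 recursion (weight `w = X'y/‖X'y‖`, score
`t = Xw`, loading `p = X't/t't`, rank-one deflation), with coefficients
`B = W(P'W)⁻¹q`; predictions are affine in the input spectrum and
successive scores are mutually orthogonal (both tested; at full rank the
coefficients equal ordinary least squares). The calibration/validation
convention is biological replicates 1–2 for training and replicate 3 held
out, exposed as a generic `train` argument. The component count is not
fixed a priori: `plsrSelectComponents()` cross-validates within the
calibration set and applies the one-standard-error rule, which matters on
small calibration sets where the PRESS minimum overfits.

## Markers and barcodes

Marker bands are those whose sign call is nonzero at ≥ 2 time points
(persistence rule; exposed as `minTimes` since published selections rarely
state their exact rule), with importance = max |D| over time. Temporal
profiles of the markers are standardized per band (shape, not magnitude,
is clustered — magnitude is already the importance) and grouped by K-means
(≥ 10 restarts) with k ∈ {2, 3, 4} chosen by the largest mean silhouette.

The RBCS pools the per-stressor markers; if the pool exceeds the target
size of 31 bands, the greedy selection keeps the largest summed importance
with ties toward the lower wavenumber and a minimal spacing of 8 cm⁻¹ —
the dense grid oversamples each physical band, and the spacing keeps one
representative grid point per band region. Whether the published 31-band
set arose from a fixed cutoff or a union-then-filter rule is not
recoverable; the ranked-union rule here is this package's own choice and
both the size and spacing are configurable. Stressor clustering flattens
each barcode (majority sign over time by default) and applies average
linkage on Hamming distances — the barcode is categorical, so counting
disagreements is the natural metric; Euclidean is available for
sensitivity analysis.

## The synthetic-spectra generator

No public instrument data accompany the methodology, so the simulator is a
first-class module that emulates the study conditions; every acceptance
check runs on its output.

Each cell is a sum of Gaussian bands (the packaged annotation table's 45
assigned bands plus 12 unassigned "nuisance" bands), a random per-cell
quadratic fluorescence baseline, a smooth random-phase harmonic background
residual (optical fringing; per-band SD 0.10 a.u.), and iid Gaussian noise
(SD 0.08 a.u. against peak amplitudes of 0.5–1.2 a.u.). Cell-to-cell
variation has two parts:

* coordinated lognormal amplitude multipliers per chemical category
  (σ = 0.15), the granularity at which regulation acts and heterogeneity
  is analysed; and
* strong *uncoordinated* lognormal variation (σ = 1.25) of the nuisance
  bands, emulating cell-state-dependent contributions such as respiratory
  chromophores and storage granules. This component dominates the
  cell-to-cell distance spread — which is what keeps whole-spectrum
  rank statistics (ANOSIM R) graded rather than saturated even when
  individual marker bands separate conditions sharply, the combination
  real ramanome data exhibits.

A stressor reshapes band *b* by the factor `exp(e_b · g_b(d) · h_b(t))`.
The exponential form keeps amplitudes positive at any effect size and
reduces to the linear `1 + e·g·h` for small effects; it was adopted
because the large multiplicative changes needed to reproduce the reported
discrimination performance leave a linear factor negative. Its parts:

* `e_b`: the per-category log-scale effect (ethanol: nucleic acids down,
  proteins/lipids/carbohydrates up; the six stressors differ in sign
  pattern and template), modulated band-by-band by a fixed factor in
  [0.5, 1.5] — real band responses within a category are not uniform.
  The magnitudes are deliberately asymmetric (reductions weaker than
  accumulations): suppression is dilution-limited while accumulation is
  not. The Cu and Cr signatures share category effects and differ in
  kinetics and a few inactive bands, encoding the strong within-family
  band sharing of the heavy metals; their per-band directions are
  stylized rather than literal.
* `g_b(d)`: a monotone dose template with `g(0) = 0`. The default is a
  saturating power law `(d/d_ref)^γ_b` whose exponents γ_b are spread
  band-specifically (0.5×–2.2× around 0.5, with a small early-saturating
  subset): low-γ bands respond at trace doses, high-γ bands keep
  separating the top of the ladder, so neighbouring doses retain distinct
  band patterns while the aggregate response grows steadily — the
  combination that yields both high dose-classification accuracy and a
  linear ANOSIM R–dose relationship. Per-band Hill curves and a plain
  proportional template are available alternatives.
* `h_b(t)`: piecewise-linear kinetic templates through the sampled time
  points with `h(0) = 0`. Each stressor has a main template (up-down for
  the alcohols, near-stable for ampicillin, down-up for Cu²⁺, complex for
  Kan and Cr⁶⁺); every band follows a fixed convex mixture of the main
  template, a slow cumulative component, and — on a band subset — an
  early-transient shock component peaking within minutes, all traversed
  at a band-specific kinetic speed (log-time warp anchored at the
  template peak). Band-individual kinetics are what keep neighbouring
  sampling times multivariately distinguishable; the transient provides
  the earliest detection signal.

Ground truth for calibration experiments records each cell's summed
category amplitudes (lipid, DNA, protein, carbohydrate) before baseline
and noise. The kanamycin-resistance scenario gives the resistant strain
5% of the sensitive effect size, so its stressed ramanome clusters with
unstressed controls; kanamycin also doubles the nucleic-acid
heterogeneity (growth-stage desynchronization under ribosome inhibition).

All per-band modulations derive from deterministic hashes of the band
center and stressor label, not from the RNG, so a signature is identical
under any simulation seed; a fixed seed makes the full output
reproducible.

### Calibration of the defaults, and what passing tests show

The generator's default effect sizes, dose exponents and kinetic templates
were calibrated once, before the test suite was frozen, so that the
simulated scenarios reproduce the qualitative and quantitative behaviour
reported for stressed *E. coli* populations: detection of the lowest
ethanol dose at 30 min with >95% accuracy, ~80–85% six-level dose
discrimination, ANOSIM R linear in dose (R² ≈ 0.94) and in early exposure
time (R² ≈ 0.91), ≥90% per-class sensitivity/specificity across nine time
points, 100% six-stressor classification, and PLSR lipid calibration with
R² ≈ 0.95. They were not adjusted afterwards.

What the simulator does *not* model: physically accurate Raman cross
sections or instrument response, shot-noise scaling with intensity (not
identifiable from published material), cosmic-ray spikes, wavenumber
miscalibration, cell-cycle structure, or time-varying heterogeneity within
a condition. Passing tests therefore demonstrate that the implementations
are correct and that the pipeline recovers planted structure under
realistic nuisance variation — not that any particular instrument's data
will reach the same numbers.

### Problem sizes

Scenario defaults follow the study layout (20 cells × 3 biological
replicates per condition; 6 ethanol doses at 30 min; 10 time points; six
stressors + matched controls at 7 time points). The test suite and the
acceptance script run these sizes directly; a handful of property tests
use reduced designs (coarser grids, fewer cells) chosen as the smallest
sizes at which the tested property is stable.

## Degenerate inputs and numerical choices

NaN intensities are load errors (a SCRS is a complete scan); all-zero
spectra cannot be normalized; temporal clustering refuses profile sets
with no structure (all profiles identical); PC-LDA caps retained
components at the LDA-feasible maximum and reports the cap; NIPALS stops
early if the response deflates to zero. Annotation lookups match the
nearest table entry within 4 cm⁻¹ (published assignments use nearby
synonyms such as 1445/1448 cm⁻¹), ties toward the lower wavenumber.
Delimiters (comma/tab) are auto-detected; descending instrument grids are
reversed on load; spectra are written at full double precision so that
write-then-read is an identity to 1e−12.

## Known limitations

The six-stressor scenario's 100% classification holds at the scenario's
strong, disjoint signatures; weaker or overlapping chemistries will not
reach it. The RBCS band count depends on the configurable selection rule,
so published band counts are not directly comparable. Replicate-level
heterogeneity testing with three replicates has limited power; the
per-cell bootstrap alternative trades pseudo-replication risk for power.
The simulator's nuisance-band model is a stylized stand-in for the many
unmodelled sources of cell-to-cell spectral variation in real
measurements.
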