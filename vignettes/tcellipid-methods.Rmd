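---
title: "Methods: quantifying T-cell lipid metabolism assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying T-cell lipid metabolism assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellipid)
```

`tcellipid` turns four interactive read-outs of T-cell lipid biology into
reproducible computations: Bodipy/PLIN2 co-localization classification,
CT-B lipid-raft metrics, dye-dilution proliferation indices, and
internal-standard lipidomics with VIP feature selection. This vignette is
the package's own account of the models behind each function, the defaults
and why they were chosen, what the simulators do and do not emulate, and
the numerical corner cases.

## Co-localization of neutral lipid and PLIN2

Canonical lipid droplets carry PLIN2 on their surface, so a cytoplasmic
Bodipy 493/503 aggregate that is a droplet should co-vary with PLIN2 pixel
by pixel. The classifier works per cell: the ROI's 50 brightest Bodipy
pixels are selected (`top_pixels()`, ties at the cutoff broken by raster
order so the subset is deterministic), and PLIN2 intensity is regressed on
Bodipy intensity by ordinary least squares with the slope t-test on
$n-2$ degrees of freedom. A cell is called co-localizing when the slope is
positive and significant at $\alpha = 0.05$.

Decisions worth making explicit:

- **Sidedness.** A "significant positive correlation ($p<0.05$)" can be
  read one- or two-sided. The default is the two-sided p value combined
  with a positive-slope requirement — the convention of standard regression
  software, and in rejection set equal to a one-sided test at 0.025. A
  `one_sided_positive` option exists; the type-I-control test uses it
  because it is the convention whose nominal rate equals $\alpha$.
- **No multiple-testing correction.** Cells are classified individually at
  raw $p < 0.05$ by design; the population statistic is the percentage of
  positive cells, not a family-wise claim.
- **Undersized cells.** Cells with fewer than 50 pixels are classified on
  all their pixels and flagged; summaries exclude them by default.
- **Degenerate fits.** Constant Bodipy over the subset (zero variance)
  yields a flagged non-positive result with $p = 1$; constant PLIN2 yields
  slope 0, $p = 1$. Both arise in background-only cells and must not crash
  a field-level run.
- **Invariance.** The slope t statistic is invariant under positive affine
  transforms of either channel, so gain/offset differences between
  acquisitions cannot change calls. This is asserted numerically in the
  tests, as is agreement of the parametric p value with a permutation
  oracle ($|\Delta p| \le 0.01$ at $n = 50$).

`intensity_profile()` reproduces the cross-sectional gray-value traces used
to eyeball co-occurrence; it is diagnostic only and takes a line's two
endpoints directly.

## Cell detection

The source studies selected one ROI per T cell manually. For
reproducibility the package replaces this with Gaussian smoothing, Otsu
thresholding (computed on the min–max normalized image, hence invariant to
positive rescaling), hole filling, connected components, and area plus
circularity filters, ordered deterministically by centroid. Circularity is
the ratio of component area to the area of the circumscribed circle — 1 for
a disk and insensitive to the perimeter-estimation bias that plagues
pixel-counted boundaries. Externally drawn label masks are supported through
`rois_from_mask()` so real data can bypass detection entirely. Touching-cell
splitting (watershed) is out of scope; the procedure presumes separable
cells, which matches the one-ROI-per-cell convention.

## Lipid raft metrics

CT-B binds ganglioside GM1, enriched in lipid rafts. Per cell the package
reports the mean CT-B fluorescence over the whole-cell ROI (total raft
abundance) and the maximal fluorescence (clustering); per field the
arithmetic mean of both across cells, one observation per field.
"Maximal fluorescence" is read as the single brightest pixel — the
cell-measurement convention of interactive image analysis tools — with a
`top_percent` alternative (mean of the brightest 1%) behind a flag for
hot-pixel robustness. Metrics run over the whole-cell ROI rather than a
membrane annulus because the assay measures CT-B fluorescence *in* T cells;
an annulus can be emulated by supplying a custom mask.

The discriminating property, verified by Monte-Carlo in the tests: at
fixed per-cell total CT-B signal, the mean is invariant to how clustered
the puncta are while the maximum is non-decreasing in the clustering
parameter. That is exactly why the assay reports both numbers.

## Dye-dilution proliferation model

A proliferation dye is halved at each division, so generations form
log2-spaced peaks. `fit_generations()` fits a one-dimensional Gaussian
mixture in log10 intensity with centers fixed at $\mu_0 - i\,\Delta$,
$\Delta = \log_{10} 2$, a single shared width $\sigma$ and free weights,
by expectation–maximization. Weights are initialized from histogram mass
within $\Delta/2$ of each center, making the fit deterministic given data
and configuration; $\sigma$ is floored at $10^{-3}$ log10 units so that
separable (near-zero-width) data converges to exact assignments instead of
a degenerate likelihood. Counts are soft (expected) assignments by
default — hard assignment is an option — and feed the two published-style
metrics: percent divided and division index (precursor-weighted mean
division number). Commercial packages fit proprietary variants of this
model (per-generation CV scaling, constrained baselines); equivalence with
them cannot be asserted, only recovery of the simulator's ground truth,
which the tests require to ±0.02 per generation fraction at 20,000 events.

$\mu_0$ defaults to the rightmost density mode of the sample itself; the
recommended source when a matched unstimulated control exists is that
control's density mode (`mu0 = "unstimulated_control_mode"`), since the
undivided peak can be nearly empty in a well-stimulated culture.
`normalize_mfi()` and `fold_change_stim()` are thin, validated wrappers for
the two MFI conventions (reference normalization and within-donor
stimulated/unstimulated ratio).

## Lipidomics quantitation

The contract starts at a species × sample intensity table with class
annotations and spiked internal-standard rows — upstream peak picking and
identification belong to instrument pipelines. Quantitation is single
point: $\mathrm{amount}(s,j) = I(s,j) / I(\mathrm{IS}_c, j) \times
\mathrm{nmol}(\mathrm{IS}_c)$ with $c$ the species' class. Any per-sample
global gain cancels in the ratio, which the tests assert. The packaged
standards map carries one standard per class with its spiked amount; where
an extraction uses two compounds of one class (ceramides, sphingoid bases)
one is designated the class standard. Ether/plasmalogen subclasses such as
PC[O] fall back to the parent-class standard via an editable alias table.
Acylcarnitines have no packaged standard and raise a coverage error unless
the user supplies one — silent mis-normalization would be worse.

Downstream conventions: per-sample normalization by protein amount or by
total lipid pool (fractions sum to 1); class profiles as per-sample class
sums over the total; differential abundance as the log2 ratio of group
means with a Welch t-test on log2 amounts (a robust default for small-n
lipidomics; amounts must be positive), annotated with the volcano tiers
$p \in \{0.05, 0.01, 0.001\}$ and the $|\log_2 FC| \ge 2$ flag, raw p by
design with an FDR column as an extra.

### VIP scores

`vip_scores()` fits PLS-DA by NIPALS: predictors autoscaled, response the
centered ±1 group indicator, two latent components by default (common
metabolomics practice; configurable, capped at the informative rank).
With unit-norm weight vectors $w_a$ and $SSY_a$ the response variance
explained by component $a$,

$$\mathrm{VIP}_j = \sqrt{p\,\frac{\sum_a SSY_a\, w_{ja}^2}{\sum_a SSY_a}},$$

so $\sum_j \mathrm{VIP}_j^2 = p$ identically and VIP > 1 selects
above-average contributors. Zero-variance species are dropped with a
warning before autoscaling. Two boundary cases are worth knowing: a single
predictor has VIP exactly 1, and two exchangeable noise-free predictors
each have VIP exactly 1 — in that noise-free limit the > 1 cutoff sits on
the boundary, which is a property of the VIP definition, not of this
implementation. The implementation is verified against an independently
coded NIPALS oracle to $10^{-6}$.

## Synthetic data: what it emulates, and what not

All four generators are seeded and bit-reproducible, with a single global
random stream per call and ground truth returned alongside the data.

- **Imaging fields** (`gen_coloc_field`, `gen_raft_field`): cells are
  non-overlapping disks placed by rejection sampling (bounded at 1000
  retries per cell — failure is a degenerate-geometry error, not an
  infinite loop). The PSF is an isotropic Gaussian implemented as an
  explicit separable convolution (truncated at $4\sigma$, replicate
  borders) so blur oracles in the tests are closed-form. The camera model
  is Poisson shot noise on signal plus background, additive Gaussian read
  noise, and 16-bit quantization with saturation — a standard confocal
  export model. Defaults (background 100, read noise 5, aggregate
  amplitude 150, membrane 400 on a 512×512 field, cell radius 10 px) put
  aggregates at peak SNR ≈ 10 and make segmentation unambiguous. In
  coupled cells the pre-noise PLIN2 at aggregate pixels is
  `coupling_slope × Bodipy + background` (default slope 0.8); raft puncta
  deposit fixed total intensity on the membrane annulus with an angular
  spread interpolating from uniform to a single arc as clustering goes
  0 → 1. Not emulated: realistic cell morphology, 3-D stacks, touching
  cells, spectral bleed-through. Passing tests therefore demonstrate
  correctness of the estimators under the stated noise and geometry model,
  not robustness to segmentation failure on crowded real fields.
- **Dye-dilution events** (`gen_ctv_events`): log-normal generations with
  exact two-fold spacing, shared width (default 0.05 log10 units), and a
  linear autofluorescence floor (default 50). The default generation
  profile (12.5/12.5/25/50% for generations 0–3) represents a
  well-stimulated culture. Not emulated: spillover, debris, doublets,
  per-generation width growth.
- **Lipid tables** (`gen_lipid_table`): log-normal measurement noise of
  specified CV, per-species amounts log-uniform within ±2 log2 units of a
  1 nmol baseline, responses anchored to the class standard so noise-free
  tables round-trip exactly, optional per-sample gain (drawn after the
  amount noise, so enabling it changes nothing but the gains), seeded
  group log2 fold-changes, and flat 100 µg protein per sample — protein
  normalization needs user-supplied values on real data.

## Problem sizes and determinism

The shipped tests and analysis scripts use fields up to 1024×1024 pixels
with 200 cells, 10-seed replicates for population-level claims, 20,000
events per cytometry sample, and lipid tables around 60 species × 16
samples — sizes at which every property under test is already stable and a
full run of the suite completes within a coffee break on one core. Every
stochastic step takes an explicit integer seed, and identical seeds with
identical parameters reproduce results bit for bit.

## Known limitations

- Detection assumes separable, roughly circular cells; crowded or
  irregular fields need externally drawn masks.
- The EM proliferation fit needs a resolvable undivided peak (directly or
  via a control); heavily skewed profiles with an empty generation 0 and
  no control fall back to the rightmost detectable mode.
- Quantitation is single-point internal-standard ratio; it inherits the
  assumption of equal response factors within a lipid class.
- VIP selection is descriptive (no permutation null is attached to the
  > 1 cutoff); pair it with the differential tests when making claims
  about individual species.
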