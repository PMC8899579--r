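---
title: "Multimodal MSI-IMC fusion: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal MSI-IMC fusion: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msifuse)
```

## The problem

Mass spectrometry imaging (DESI-MSI) measures where a drug and its
metabolites sit in a tissue section, at a pixel pitch of 50 µm × 75 µm, but
it does not know what the tissue under each pixel is. Imaging mass cytometry
(IMC) resolves single cells with a 27-marker antibody panel — enough to call
tumor cells, fibroblasts, vasculature and myeloid populations — but carries
no drug signal. `msifuse` integrates the two modalities acquired from the
same section: it gates IMC cells into phenotypes, classifies their tissue
context, co-registers the IMC frame onto the MSI frame, transfers tissue
labels from cells to MSI pixels, generalizes those labels to every pixel
with a k-nearest-neighbor classifier, and then asks the pharmacological
questions — which tissue features correlate with drug abundance, which cell
populations are enriched where drug is high, and what fraction of the total
drug signal sits in the tumor versus the stromal compartment.

## Pipeline stages and the choices behind them

### Preprocessing

The MSI side enters as peak-reduced spectra (imzML, continuous or processed
mode); centroiding from profile data is upstream of this package.
Background pixels are found by k-means (`detect_background`, k = 2 by
default) on standardized **log** intensity features: log TIC plus the ten
highest-variance peaks. The log matters — on linear features the dominant
variance direction is between tissue classes, and k-means happily splits
tumor from stroma while leaving the glass background attached to one of
them. Clusters whose mean TIC falls below the brightest cluster's mean
divided by `min_contrast` (default 5) are called background; if no cluster
is that dim the section is treated as all tissue rather than inventing a
background.

Spectra are TIC-normalized for classification (`tic_normalize`; each pixel's
peak vector sums to one, idempotent by construction). Drug quantification
uses ion images extracted from the *raw* intensities — per-pixel sums over
an m/z window, e.g. ±0.005 Th for the structural-analogue reference ion —
optionally divided by that reference image (`normalize_to_reference`).
Pixels whose reference falls below the 1st percentile of positive reference
values are marked invalid instead of producing unstable ratios. Compartment
fractions are invariant to any positive rescaling of the drug image, so raw
and reference-normalized images give identical fractions.

### Gating and cell tissue classification

Marker positivity is a threshold on mean intensity, boundary-inclusive
(`intensity >= threshold` is positive; the convention had to be fixed one
way and inclusive matches the natural reading of "set manually"). The six
myeloid gates share the CD45+ CD11b+ (F4/80+ **or** CD68+) core; the
published M1/M2 sub-gates do not repeat the base macrophage exclusions
(CD11c−, Ly6G−), and we read them literally by default
(`default_phenotype_rules(inherit_exclusions = FALSE)`), with the stricter
inherited variant behind the flag. Membership is multi-label; a single
primary label is resolved by the precedence neutrophil > dendritic cell >
M2 > M1 > immature monocyte > macrophage, ordered from most to least
specific gate.

Cell tissue context (tumor / connective / necrosis) is a supervised
contract: any classifier reaching the accuracy bar is acceptable, and we
use a random forest on log1p marker intensities (200 trees, no tuning) —
robust to the skewed, collinear intensities, and deterministic given the
seed.

### Co-registration

All geometry is done in physical micrometres; because MSI pixels are
anisotropic (50 × 75 µm), both representative images are resampled to a
common isotropic 25 µm working grid before any similarity metric is
evaluated. The fixed image is the TIC image; the moving image is a binned,
lightly smoothed raster of total marker intensity per cell. Raster bins far
from any cell were never imaged, not dark — they are masked out, which
matters whenever IMC covers only part of the section.

The estimator is multi-resolution (200/100/50/25 µm): a dense deterministic
sweep over rotation × translation at the coarsest level (a centroid init
can be several hundred µm off under partial coverage), Nelder-Mead under
normalized cross-correlation down the pyramid with the isotropic scale
bounded to [0.8, 1.25] (serial sections cannot differ much in scale), and a
final refinement under 32-bin mutual information — NCC has the wide capture
range, but its optimum is biased by the nonlinear intensity relation
between a TIC field and a cell-intensity raster, which MI tolerates.
Because the MI surface is rugged at histogram scale, the refinement scans a
local grid and polishes the strongest candidates rather than trusting a
single descent. A closed-form landmark mode (`fit_affine_landmarks`) is the
fully deterministic alternative when point pairs exist. On the synthetic
benchmark the planted similarity transform (10°, scale 1.05, (250, −150) µm)
is recovered with a mean corner error of 6–15 µm — well under half an MSI
x-pixel.

Cells map into pixels by the half-open convention: pixel `(ix, iy)` covers
`[ix·50, (ix+1)·50) × [iy·75, (iy+1)·75)` µm, so a cell exactly on a
boundary belongs to the higher-indexed pixel. Out-of-grid cells are flagged,
never dropped.

### Label transfer

A pixel takes a tissue class when **strictly more than half** of its cells
carry that class; an exact 50/50 split stays unassigned. A kNN classifier
(k = 30) is then fit on all vote-labeled pixels plus a background class
drawn from the k-means background — capped at the median per-class training
count to avoid swamping the tissue classes — and predicts every pixel of the
dataset, including regions IMC never saw. Features are the TIC-normalized,
per-peak standardized intensities; standardization stops high-abundance
lipid peaks from dominating the Euclidean metric. The drug, metabolite and
reference ions are excluded from the feature set by default so tissue
classification is never driven by the analyte being quantified. Ties break
by smallest aggregate neighbor distance, then by the fixed class order
tumor < connective < necrosis < background, making prediction fully
deterministic.

### Cross-modal analysis and quantification

Marker maps are per-pixel aggregates over the cells in each pixel; pixels
with no cells are missing, not zero, and correlations (plain Pearson) run
over jointly valid pixels only. High/low drug stratification splits a region
at its median drug intensity — parameter-free; other quantiles are an
option. Enrichment is reported as phenotype-positive cells per mm² of mask
area (nominal pixel area 3,750 µm²), high over low; densities are computed
only within the IMC-covered part of the section, since area without imaged
cells would dilute them. An endothelial "phenotype" for enrichment is simply
CD31 positivity. Compartment drug fractions divide the drug signal summed
over a class's pixels by the sum over all tissue classes; necrosis counts as
tissue in the denominator by default (excludable).

## The synthetic-data generator

No suitable paired MSI + IMC dataset is publicly deposited, so validation
runs on generated data whose every planted quantity is known. The generator
emulates, under one master seed (split per sub-generator, so one stage's
draws never perturb another's):

- **Tissue geometry**: a rotated ellipse of tissue on a 128 × 128 grid of
  50 × 75 µm pixels, partitioned into 40 Voronoi regions; regions are
  assigned to tumor/connective/necrosis by a greedy largest-first rule so
  realized pixel fractions track the priors (0.5, 0.3, 0.2). Contiguous
  regions give the spatial autocorrelation that registration and
  correlation analyses need.
- **Spectra**: 36 tissue peaks; each class over-expresses a third of them
  4-fold, and overall signal levels differ by class (1 : 0.75 : 0.35 —
  necrotic tissue ionizes poorly), which gives the TIC image the mosaic
  contrast real sections show. Noise is multiplicative log-normal
  (mean-preserving, sdlog 0.3) — MSI intensities are nonnegative and
  right-skewed. Background pixels carry 0.5% of the tissue signal.
- **Drug field**: noise-free drug = class baseline + 0.08 × local planted
  M2 density (cells/mm²), sdlog 0.25. Connective regions split into
  high/low drug zones; the coupling makes high-drug stroma genuinely
  macrophage-enriched, as observed in the motivating system. Zones are
  balanced by their area inside the IMC acquisition rectangle — the
  acquisition region is deliberately placed over heterogeneous drug
  content, so the analyzed stroma holds both zones in comparable amounts.
  The connective baseline (2.303) is solved so that roughly 45% of the
  total noise-free drug signal falls in the tumor compartment; the truth
  object records the exact realized value.
- **Cells**: independent Poisson point processes per (class, phenotype)
  with densities 800/600/60 cells/mm² and class-specific phenotype mixes;
  high-drug stroma multiplies M2 density by 5.1 and endothelial density by
  1.8 (the planted enrichment folds). Marker intensities are log-normal
  around three tiers (negative ≈ 0.5, moderate ≈ 8, positive ≈ 30 counts,
  sdlog 0.4) per phenotype, plus additive class-context shifts on ECM and
  damage channels (collagen in stroma, cleaved caspase-3 and GLUT1 in
  necrosis) — the spillover that lets a classifier recover a macrophage's
  tissue context. Cell coordinates are emitted in an IMC frame displaced by
  the truth similarity transform (10°, scale 1.05, (250, −150) µm).

What the generator does **not** emulate: profile spectra, isotope patterns
or detector physics; segmentation errors and marker spillover between
neighboring cells; nonrigid section deformation (the truth transform is a
similarity); spatial gradients within a tissue region. Passing tests
therefore demonstrate that the pipeline's logic is correct and its
estimators recover planted truth under realistic noise — not that any
specific biological dataset would yield these numbers.

## Validation design and problem sizes

The validation suite (mirrored by `scripts/acceptance.R`) checks, at the
default 128 × 128 / ~18,000-cell scale unless noted:

- gating against an independently hand-written truth table on 1,000 cells
  covering all 64 core-marker combinations and threshold-boundary cases;
- the strict majority vote against an exhaustive counting oracle on 200
  random instances up to 10 × 10;
- kNN label transfer (k = 30, analyte ions excluded): pixel accuracy ≥ 0.95
  against the truth map, and k = 1 self-consistency of 100% on vote pixels;
- registration on five seeds: mean corner error < 25 µm (half an MSI
  x-pixel), scale within 1%;
- Pearson recovery of a planted ρ = 0.7 at 10⁴ pixels within the Fisher-z
  99% interval on ten seeds;
- recovery of the planted 5.1-fold M2 stromal enrichment within ±20%
  relative (median split) on ten seeds, alongside the 1.8-fold endothelial
  enrichment;
- recovery of the planted ≈ 0.45 tumor drug fraction within ±0.02 using
  truth labels and ±0.05 using kNN-predicted labels;
- bit-identical `summary.json` across two full pipeline runs (file I/O,
  registration and all) with the same configuration and seed.

## Numerical details worth knowing

- All randomness descends from one integer seed through named streams
  (`split_seed`), so results are reproducible to the bit and stages are
  decoupled.
- The vote rule is strict (`> 0.5`); ties are unassigned by design.
- Bilinear interpolation treats pixel values as point samples at pixel
  centres; sampling outside a grid yields NA, which every metric treats as
  "no data".
- Log-normal noise is mean-preserving (`meanlog = log(v) − σ²/2`), so
  planted means survive noising.
- `tic_normalize` drops (with a warning) tissue pixels whose TIC is zero —
  they cannot be normalized and would poison the kNN feature space.
- A constant image is rejected by registration ("no contrast") rather than
  silently returning the identity.

## Known limitations

- The kNN features assume a shared peak list across pixels (peak-reduced
  data); profile or per-pixel-centroided data must be re-binned upstream.
- Intensity-based registration assumes the two modalities share gross
  morphology (tissue outline, necrosis holes, density contrast); a section
  with no interior contrast will register poorly — use landmark mode.
- Enrichment folds are undefined when the low-drug stratum holds no cells
  of a phenotype; the report flags this instead of returning infinity.
- Pearson correlations carry no spatial-autocorrelation correction; treat
  their nominal p-values (not reported) with suspicion.
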