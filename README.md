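# msifuse

Tumors are not homogeneous: a nanomedicine-delivered drug may pool in the
stroma, hug the vasculature, or reach the tumor cells themselves, and bulk
LC-MS numbers cannot tell these apart. `msifuse` integrates two imaging
modalities acquired from the *same* tissue section to resolve this:

- **DESI-MSI** — a mass spectrum per pixel (50 µm × 75 µm raster, negative
  mode, m/z 250–1000) carrying the drug, metabolite and reference-analogue
  ion signal;
- **IMC** — segmented single cells with a 27-marker antibody panel,
  resolving tumor cells, fibroblasts, endothelium and myeloid populations.

It is written for imaging mass spectrometrists and spatial-biology analysts
who need compartment-resolved drug quantification in R.

## What it does

1. **MSI preprocessing** — imzML read/write, k-means background detection,
   TIC normalization, ion-image extraction (e.g. the reference window
   m/z 520.2492 ± 0.005), reference-analogue normalization.
2. **IMC gating** — threshold positivity, then the standard myeloid gates,
   e.g. M2 macrophage = CD45+ CD11b+ (F4/80+ or CD68+) CD163+ CD206+;
   random-forest cell tissue classification (tumor / connective / necrosis).
3. **Co-registration** — multi-resolution intensity-based estimation of the
   IMC→MSI similarity/affine transform (NCC pyramid + mutual-information
   refinement), or closed-form landmark fits; cells are mapped into MSI
   pixels by the half-open 50 × 75 µm convention.
4. **Label transfer** — an MSI pixel takes a tissue class when strictly
   more than 50% of its cells carry it; a kNN classifier (k = 30, plus a
   background class) then labels every pixel, including regions IMC never
   covered:

   ```
   label(p) = majority vote  if  max_c  n_c(p) / n(p) > 1/2
   knn(p)   = argmax_c  #{ i in N_30(p) : y_i = c }
   ```

   on TIC-normalized, per-peak standardized spectra with the analyte ions
   excluded.
5. **Cross-modal analysis** — Pearson correlation of marker maps with ion
   images; median-split high/low drug stratification of the stroma;
   phenotype enrichment folds (cells per mm² in high- vs low-drug stroma);
   compartment drug fractions `f_c = Σ_{p: label(p)=c} drug(p) / Σ_tissue drug(p)`
   and their timecourse summary.
6. **Synthetic ground truth** — a generator producing paired MSI + IMC
   datasets (Voronoi tissue mosaics, class-dependent peak templates,
   a drug ion coupled to planted M2-macrophage density, Poisson cell
   patterns, a known inter-modality transform) so every stage is testable
   without any download.

## Worked example

```r
library(msifuse)

b <- generate_dataset(synth_config(seed = 1))   # paired data + ground truth
b
#> <synth_bundle> seed 1: 16384 MSI pixels, 17818 cells, planted tumor drug fraction 0.466

cfg <- pipeline_config(bundle = b, out_dir = "run1",
                       registration = list(mode = "truth"), seed = 1)
s <- run_pipeline(cfg)

round(s$pixel_label_accuracy, 3)                  # kNN labels vs truth map
#> 1
round(s$enrichment$M2_macrophage$fold, 2)         # planted: 5.1
#> 4.89
round(s$enrichment$endothelial$fold, 2)           # planted: 1.8
#> 1.74
round(s$drug_fraction_predicted_labels$tumor, 3)  # planted: 0.466
#> 0.465
round(s$correlations$CD206$r, 3)                  # drug co-varies with M2 markers
#> 0.42
```

Reading the numbers: every MSI pixel received the correct tissue class; the
median split of stromal drug signal recovered the planted 5.1-fold M2 and
1.8-fold endothelial enrichment within their sampling error; 46.5% of the
drug signal was attributed to the tumor compartment against a planted 46.6%;
and the drug image correlates positively with macrophage markers, as it
should given the planted drug–macrophage coupling. `run1/` holds the
predicted label map, per-class mean ion intensities, the transform and a
`summary.json` that is bit-identical across reruns.

To estimate the registration instead of using the known truth transform,
drop the `registration` argument (the default is intensity-based
estimation), or call `estimate_transform()` directly on
`representative_image_msi(ds)` and `representative_image_imc(cells)`.

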