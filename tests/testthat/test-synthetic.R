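test_that("configuration invariants are enforced", {
  expect_error(synth_config(class_priors = c(tumor = 0.6, connective = 0.3,
                                             necrosis = 0.3)), "sum to 1")
  expect_error(synth_config(grid_nx = 4), ">= 8")
  expect_error(synth_config(cell_density_per_class = c(tumor = -1,
                                                       connective = 1,
                                                       necrosis = 1)),
               "nonnegative")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_synth_config(seed = 3)
  a <- generate_dataset(cfg); b <- generate_dataset(cfg)
  expect_identical(a$msi$intensities, b$msi$intensities)
  expect_identical(a$truth$label_map$labels, b$truth$label_map$labels)
  expect_identical(as.data.frame(a$cells), as.data.frame(b$cells))
  d <- generate_dataset(small_synth_config(seed = 4))
  expect_false(identical(a$msi$intensities, d$msi$intensities))
})

test_that("a degenerate prior paints all tissue with one class", {
  lm <- generate_tissue_map(small_synth_config(
    class_priors = c(tumor = 1, connective = 0, necrosis = 0)))
  tissue <- lm$labels != "background"
  expect_true(all(lm$labels[tissue] == "tumor"))
})

test_that("realized class fractions track the priors", {
  lm <- generate_tissue_map(synth_config(seed = 7))
  tissue <- lm$labels != "background"
  frac <- table(factor(lm$labels[tissue], tissue_classes())) / sum(tissue)
  expect_true(all(abs(frac - c(0.5, 0.3, 0.2)) < 0.10))
})

test_that("noise-free tumor pixels equal the template exactly", {
  cfg <- small_synth_config(peak_sdlog = 0, drug_sdlog = 0,
                            reference_sdlog = 0)
  lm <- generate_tissue_map(cfg)
  ds <- generate_msi(lm, cfg)
  tum <- which(as.vector(lm$labels) == "tumor")
  non_analyte <- !(ds$mz %in% c(cfg$drug_mz, cfg$metabolite_mz, cfg$reference_mz))
  expect_equal(unname(ds$intensities[tum[1], non_analyte]),
               unname(cfg$peak_templates[1, order(cfg$peak_mz)]))
  expect_equal(ds$intensities[tum[1], non_analyte],
               ds$intensities[tum[2], non_analyte])
})

test_that("drug means order with the planted baselines", {
  cfg <- small_synth_config(seed = 2,
                            drug_baseline = c(tumor = 1, connective = 40,
                                              necrosis = 0.5))
  lm <- generate_tissue_map(cfg)
  ds <- generate_msi(lm, cfg)
  drug <- ds$intensities[, which.min(abs(ds$mz - cfg$drug_mz))]
  lab <- as.vector(lm$labels)
  expect_gt(mean(drug[lab == "connective"]), mean(drug[lab == "tumor"]))
})

test_that("background pixels carry under 1% of median tissue TIC", {
  b <- generate_dataset(small_synth_config(seed = 5))
  tic <- msi_tic(b$msi)
  lab <- as.vector(b$truth$label_map$labels)
  expect_lt(max(tic[lab == "background"]),
            0.01 * stats::median(tic[lab != "background"]))
})

test_that("missing template for a present class is a configuration error", {
  cfg <- small_synth_config()
  lm <- generate_tissue_map(cfg)
  cfg$peak_templates <- cfg$peak_templates[1:2, ]
  rownames(cfg$peak_templates) <- c("tumor", "connective")
  expect_error(generate_msi(lm, cfg), "no peak template")
})

test_that("cell counts match the closed-form Poisson expectation", {
  # uniform 100 cells/mm^2 over a full 128 x 128 grid of 50 x 75 um pixels:
  # expectation 100 * (128 * 0.050) * (128 * 0.075) = 6144
  cfg <- synth_config(cell_density_per_class = c(tumor = 100, connective = 100,
                                                 necrosis = 100),
                      imc_roi_fraction = 1, seed = 8)
  labels <- matrix("tumor", 128, 128)
  lm <- tissue_label_map(labels)
  cells <- generate_cells(lm, cfg)
  expected <- 6144
  expect_lt(abs(nrow(cells) - expected), 3 * sqrt(expected))
})

test_that("no cells appear where the density is zero", {
  cfg <- synth_config(grid_nx = 48, grid_ny = 48, n_tissue_regions = 12,
                      cell_density_per_class = c(tumor = 400,
                                                 connective = 300,
                                                 necrosis = 0))
  lm <- generate_tissue_map(cfg)
  cells <- generate_cells(lm, cfg)
  expect_false(any(attr(cells, "truth")$tissue_class == "necrosis"))
})

test_that("a degenerate phenotype mix gates every connective cell M2", {
  z <- setNames(numeric(10), msifuse:::synthetic_phenotypes())
  mixes <- list(tumor = replace(z, "tumor_cell", 1),
                connective = replace(z, "M2_macrophage", 1),
                necrosis = replace(z, "debris", 1))
  cfg <- small_synth_config(phenotype_mix_per_class = mixes, marker_sdlog = 0)
  lm <- generate_tissue_map(cfg)
  cells <- generate_cells(lm, cfg)
  cells <- assign_phenotypes(apply_thresholds(cells, default_thresholds()))
  conn <- attr(cells, "truth")$tissue_class == "connective"
  expect_true(all(cells$phenotype[conn] == "M2_macrophage"))
})

test_that("every generated cell maps back inside the tissue mask", {
  b <- generate_dataset(small_synth_config(seed = 6))
  p <- affine_apply(b$truth$transform, cbind(b$cells$x_um, b$cells$y_um))
  ix <- floor(p[, 1] / 50); iy <- floor(p[, 2] / 75)
  lab <- b$truth$label_map$labels[cbind(iy + 1, ix + 1)]
  expect_true(all(lab != "background"))
})

test_that("the recorded drug fraction equals the noise-free field ratio", {
  b <- generate_dataset(small_synth_config(seed = 7))
  lab <- as.vector(b$truth$label_map$labels)
  nf <- b$truth$noise_free_drug
  expect_equal(b$truth$planted_tumor_drug_fraction,
               sum(nf[lab == "tumor"]) / sum(nf[lab != "background"]),
               tolerance = 1e-12)
})
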