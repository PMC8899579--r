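# Validation benchmarks: each function generates synthetic data with known
# ground truth under the default study conditions, runs the corresponding
# pipeline stage(s), and returns the measured quantity next to the planted
# one. They back both the package's validation tests and the reproduction
# script.

#' Label-transfer benchmark
#'
#' Runs the full cell-to-pixel chain on the default synthetic benchmark:
#' background detection, TIC normalization, marker gating, random-forest
#' cell tissue classification (trained on a truth-labeled subset), transfer
#' through the ground-truth transform, strict majority vote and kNN
#' classification of every pixel. Reports pixel accuracy against the truth
#' label map, k = 1 self-consistency on the vote-labeled pixels, and the
#' tumor drug fraction recovered with truth and with predicted labels.
#'
#' @param seed generator seed
#' @param k number of kNN neighbors
#' @param train_fraction fraction of cells used to train the cell classifier
#' @return a list of measured and planted quantities
#' @export
benchmark_label_transfer <- function(seed = 23, k = 30, train_fraction = 0.3) {
  b <- generate_dataset(synth_config(seed = seed))
  ds <- detect_background(b$msi, seed = seed)
  ds_tic <- tic_normalize(ds)
  cells <- apply_thresholds(b$cells, default_thresholds())
  cells <- assign_phenotypes(cells)
  truth_lab <- b$truth$cell_truth$tissue_class
  set.seed(split_seed(seed, "train-split"))
  idx <- unlist(lapply(split(seq_len(nrow(cells)), truth_lab), function(i)
    sample(i, max(20, round(train_fraction * length(i))))))
  train <- cells[idx, ]
  train$tissue_class <- truth_lab[idx]
  class(train) <- class(cells)
  attr(train, "markers") <- cell_markers(cells)
  cells <- classify_cell_tissue(train, cells, seed = seed)
  cell_acc <- mean(cells$tissue_class == truth_lab)

  cells <- transform_cells(cells, b$truth$transform, ds)
  vote <- majority_vote_labels(cells, ds)
  excl <- default_ions()$mz
  labels <- fit_predict_knn(ds_tic, vote, k = k, exclude_mz = excl)
  tm <- b$truth$label_map$labels
  pixel_acc <- mean(labels$labels == tm)

  self1 <- fit_predict_knn(ds_tic, vote, k = 1, exclude_mz = excl)
  vote_px <- vote$labels %in% tissue_classes()
  self_acc <- mean((self1$labels == vote$labels)[vote_px])

  drug <- extract_ion_image(ds, default_ions()$mz[1], default_ions()$tol[1])
  fr_truth <- drug_fraction_by_class(drug, b$truth$label_map)
  fr_pred <- drug_fraction_by_class(drug, labels)
  list(pixel_accuracy = pixel_acc,
       knn_self_consistency = self_acc,
       cell_class_accuracy = cell_acc,
       vote_pixel_count = sum(vote_px),
       n_pixels = length(tm),
       fraction_truth_labels = fr_truth$fraction[fr_truth$class == "tumor"],
       fraction_knn_labels = fr_pred$fraction[fr_pred$class == "tumor"],
       planted_fraction = b$truth$planted_tumor_drug_fraction)
}

#' Registration benchmark
#'
#' For each seed, generates a paired dataset whose IMC frame is displaced by
#' the planted similarity transform (10 deg, scale 1.05, (250, -150) um),
#' estimates the transform from the representative images alone, and
#' reports the mean corner displacement (um) over the IMC field of view plus
#' the recovered scale.
#'
#' @param seeds integer vector of generator seeds
#' @return data frame (seed, corner_error_um, scale, metric_value)
#' @export
benchmark_registration <- function(seeds = 1:5) {
  rows <- lapply(seeds, function(sd) {
    b <- generate_dataset(synth_config(seed = sd))
    ds <- detect_background(b$msi, seed = sd)
    est <- estimate_transform(representative_image_msi(ds),
                              representative_image_imc(b$cells))
    ex <- diff(range(b$cells$x_um)); ey <- diff(range(b$cells$y_um))
    corners <- cbind(min(b$cells$x_um) + c(0, ex, ex, 0),
                     min(b$cells$y_um) + c(0, 0, ey, ey))
    data.frame(seed = sd,
               corner_error_um = mean_corner_error(est$transform,
                                                   b$truth$transform, corners),
               scale = sqrt(abs(det(est$transform$A))),
               metric_value = est$report$similarity_metric_value)
  })
  do.call(rbind, rows)
}

#' Correlation-recovery benchmark
#'
#' Plants a known Pearson correlation between a marker map and an ion image
#' at `nx * ny` pixels and reports the recovered coefficient per seed,
#' together with the Fisher-z interval at the requested confidence.
#'
#' @param seeds integer vector of seeds
#' @param rho planted correlation
#' @param nx,ny map size (defaults give 10^4 pixels)
#' @param conf confidence level for the Fisher-z interval
#' @return list(r = per-seed correlations, lower, upper)
#' @export
benchmark_correlation <- function(seeds = 1:10, rho = 0.7, nx = 100, ny = 100,
                                  conf = 0.99) {
  r <- vapply(seeds, function(sd) {
    sim <- simulate_correlated_maps(nx = nx, ny = ny, rho = rho, seed = sd)
    pearson_map_correlation(sim$marker_map, sim$ion)$r
  }, 0)
  z <- atanh(rho)
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(nx * ny - 3)
  list(r = r, lower = tanh(z - hw), upper = tanh(z + hw), n = nx * ny)
}

#' Enrichment-recovery benchmark
#'
#' For each seed: generate, gate, map cells through the truth transform,
#' median-split the stromal drug signal within the IMC-covered area, and
#' report the recovered M2-macrophage and endothelial (CD31+) enrichment
#' folds next to the planted ones (5.1 and 1.8 under defaults).
#'
#' @param seeds integer vector of generator seeds
#' @return data frame (seed, fold_m2, fold_endothelial) with attribute
#'   `"planted"`
#' @export
benchmark_enrichment <- function(seeds = 1:10) {
  planted <- NULL
  rows <- lapply(seeds, function(sd) {
    b <- generate_dataset(synth_config(seed = sd))
    planted <<- b$truth$planted_enrichment_folds
    drug <- extract_ion_image(b$msi, default_ions()$mz[1], default_ions()$tol[1])
    cells <- apply_thresholds(b$cells, default_thresholds())
    cells <- assign_phenotypes(cells)
    cells$is_endothelial <- cells$positive_CD31
    cells <- transform_cells(cells, b$truth$transform, b$msi)
    inb <- cells$in_bounds
    cov <- matrix(FALSE, b$msi$ny, b$msi$nx)
    cov[(min(cells$iy[inb]):max(cells$iy[inb])) + 1L,
        (min(cells$ix[inb]):max(cells$ix[inb])) + 1L] <- TRUE
    stroma <- b$truth$label_map$labels == "connective" & cov
    st <- stratify_high_low(drug, region_mask = stroma)
    en <- phenotype_enrichment(cells, st$high, st$low, b$msi,
                               c("M2_macrophage", "endothelial"))
    data.frame(seed = sd, fold_m2 = en$fold[1], fold_endothelial = en$fold[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "planted") <- planted
  out
}

#' Determinism benchmark
#'
#' Writes a synthetic bundle to disk and runs the full pipeline twice from
#' the files with identical configuration and seed (including
#' intensity-based registration), returning whether the two summary JSON
#' files are byte-identical.
#'
#' @param seed master seed
#' @param dir scratch directory
#' @return list(identical = logical, summary = first run's summary list)
#' @export
benchmark_determinism <- function(seed = 1, dir = tempfile("msifuse_det_")) {
  synth_dir <- file.path(dir, "synth")
  run_synth(synth_config(seed = seed), synth_dir)
  raws <- lapply(1:2, function(i) {
    pc <- pipeline_config(msi_path = file.path(synth_dir, "msi.imzML"),
                          cells_path = file.path(synth_dir, "cells.csv"),
                          out_dir = file.path(dir, paste0("run", i)),
                          seed = seed)
    s <- run_pipeline(pc, truth_path = file.path(synth_dir, "truth.yaml"))
    p <- file.path(pc$out_dir, "summary.json")
    list(bytes = readBin(p, "raw", file.info(p)$size), summary = s)
  })
  list(identical = identical(raws[[1]]$bytes, raws[[2]]$bytes),
       summary = raws[[1]]$summary)
}
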