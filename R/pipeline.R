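# End-to-end orchestration: synthesize a dataset bundle to disk, and run the
# full analysis (preprocess -> gate -> register -> vote -> kNN -> correlate
# -> quantify) from a single configuration with one master seed.

#' Default gating thresholds (intensity counts) for the panel
#' @export
default_thresholds <- function() {
  stats::setNames(rep(5, length(panel_markers())), panel_markers())
}

#' Default ions of interest: drug, metabolite and reference windows
#' @export
default_ions <- function() {
  data.frame(name = c("drug", "metabolite", "reference"),
             mz = c(507.25, 478.26, 520.2492),
             tol = c(0.3, 0.3, 0.005))
}

#' Pipeline configuration
#'
#' @param msi_path path to an imzML file (ignored when `bundle` given)
#' @param cells_path path to a cell CSV (ignored when `bundle` given)
#' @param bundle optional in-memory `synth_bundle` (truth-aware run)
#' @param out_dir output directory
#' @param thresholds named marker thresholds
#' @param rules phenotype gating rules
#' @param registration list(mode = "intensity"|"truth", metric, model)
#' @param knn list(k, exclude_analytes)
#' @param ions data frame (name, mz, tol) of ions of interest
#' @param correlation_markers markers correlated against the drug image
#' @param train_fraction fraction of truth-labeled cells used to train the
#'   cell tissue classifier
#' @param seed master seed for every stochastic stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(msi_path = NULL, cells_path = NULL, bundle = NULL,
                            out_dir = tempfile("msifuse_run_"),
                            thresholds = default_thresholds(),
                            rules = default_phenotype_rules(),
                            registration = list(mode = "intensity",
                                                metric = "ncc",
                                                model = "similarity"),
                            knn = list(k = 30, exclude_analytes = TRUE),
                            ions = default_ions(),
                            correlation_markers = c("CD68", "CD206", "CD163",
                                                    "Collagen1", "aSMA",
                                                    "CD31", "Ly6G"),
                            train_fraction = 0.3, seed = 1) {
  if (is.null(bundle)) {
    for (p in c(msi_path, cells_path)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
  }
  stopifnot(knn$k >= 1, all(ions$tol > 0), train_fraction > 0,
            train_fraction <= 1)
  structure(list(msi_path = msi_path, cells_path = cells_path,
                 bundle = bundle, out_dir = out_dir, thresholds = thresholds,
                 rules = rules, registration = registration, knn = knn,
                 ions = ions, correlation_markers = correlation_markers,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a synthetic dataset bundle to disk
#'
#' Generates the paired dataset and writes the MSI as imzML, the cells as
#' CSV, the ground truth as a YAML sidecar (with label-map and cell-truth
#' CSVs alongside), and a manifest recording the seed and content hashes, so
#' a rerun with the same configuration is verifiably identical.
#'
#' @param config a `synth_config`
#' @param out_dir output directory (created if missing)
#' @param mode imzML mode, `"continuous"` or `"processed"`
#' @return invisibly, the list of written paths
#' @export
run_synth <- function(config = synth_config(), out_dir, mode = "continuous") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  bundle <- generate_dataset(config)
  paths <- list(
    msi = file.path(out_dir, "msi.imzML"),
    ibd = file.path(out_dir, "msi.ibd"),
    cells = file.path(out_dir, "cells.csv"),
    truth = file.path(out_dir, "truth.yaml"),
    label_map = file.path(out_dir, "label_map_truth.csv"),
    cell_truth = file.path(out_dir, "cell_truth.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_imzml(bundle$msi, paths$msi, mode = mode)
  write_cells(bundle$cells, paths$cells)
  write_label_map(bundle$truth$label_map, paths$label_map)
  utils::write.csv(bundle$truth$cell_truth, paths$cell_truth,
                   row.names = FALSE, quote = FALSE)
  tr <- config$transform_truth
  yaml::write_yaml(list(
    planted_tumor_drug_fraction = bundle$truth$planted_tumor_drug_fraction,
    planted_enrichment_folds = as.list(bundle$truth$planted_enrichment_folds),
    planted_marker_ion_correlations =
      as.list(bundle$truth$planted_marker_ion_correlations),
    transform = list(rotation_deg = tr$rotation_deg, scale = tr$scale,
                     translation_um = tr$translation_um),
    imc_roi = as.list(bundle$truth$imc_roi),
    files = list(label_map = basename(paths$label_map),
                 cell_truth = basename(paths$cell_truth))), paths$truth)
  hash_file <- function(p) content_hex(readBin(p, "raw", file.info(p)$size))
  jsonlite::write_json(list(
    seed = config$seed,
    config_hash = fnv1a_hex(paste(deparse(unclass(config)), collapse = "")),
    files = lapply(paths[c("msi", "ibd", "cells", "truth", "label_map",
                           "cell_truth")],
                   function(p) list(name = basename(p),
                                    bytes = file.info(p)$size,
                                    fnv1a = hash_file(p)))),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

load_truth_sidecar <- function(truth_path) {
  y <- yaml::read_yaml(truth_path)
  dirn <- dirname(truth_path)
  lm <- utils::read.csv(file.path(dirn, y$files$label_map))
  ny <- max(lm$iy) + 1L; nx <- max(lm$ix) + 1L
  labels <- matrix("unassigned", ny, nx)
  labels[lm$iy + 1L + ny * lm$ix] <- lm$label
  list(label_map = tissue_label_map(labels),
       transform = similarity2d(y$transform$rotation_deg, y$transform$scale,
                                unlist(y$transform$translation_um)),
       planted_tumor_drug_fraction = y$planted_tumor_drug_fraction,
       planted_enrichment_folds = unlist(y$planted_enrichment_folds),
       cell_truth = utils::read.csv(file.path(dirn, y$files$cell_truth)))
}

#' Run the full fusion pipeline
#'
#' Executes every stage in the canonical order — background detection and
#' TIC normalization, marker gating and phenotype assignment, cell tissue
#' classification, co-registration, cell-to-pixel transfer, majority vote,
#' kNN classification of all pixels, cross-modal correlations, high/low
#' drug stromal enrichment, and compartment drug fractions — and writes all
#' stage outputs plus a single `summary.json` to the output directory.
#' When ground truth is available (synthetic bundle or truth sidecar) the
#' summary additionally reports accuracies against it. Fully deterministic
#' given configuration and seed. On a stage failure a
#' `FAILED_<stage>` marker file is left in the output directory and the
#' error is rethrown.
#'
#' @param config a `pipeline_config`
#' @param truth_path optional truth YAML sidecar (as written by [run_synth()])
#' @return invisibly, the summary list
#' @export
run_pipeline <- function(config, truth_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- "load"
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out, paste0("FAILED_", stage)))
    stop(e)
  }
  tryCatch({
    log_lines <- c(paste("msifuse pipeline, seed", seed),
                   paste("stage order: preprocess gate classify register",
                         "vote knn correlate quantify"))
    truth <- NULL
    if (!is.null(config$bundle)) {
      ds_raw <- config$bundle$msi
      cells <- config$bundle$cells
      truth <- config$bundle$truth
    } else {
      ds_raw <- read_imzml(config$msi_path)
      cells <- read_cells(config$cells_path)
      if (!is.null(truth_path)) truth <- load_truth_sidecar(truth_path)
    }

    stage <- "preprocess"
    ds_raw <- detect_background(ds_raw, seed = seed)
    ds_tic <- tic_normalize(ds_raw)
    ions <- config$ions
    ion_imgs <- lapply(seq_len(nrow(ions)), function(i)
      extract_ion_image(ds_raw, ions$mz[i], ions$tol[i]))
    names(ion_imgs) <- ions$name
    drug_img <- ion_imgs[["drug"]] %||% ion_imgs[[1]]
    drug_norm <- if (!is.null(ion_imgs[["reference"]]))
      normalize_to_reference(drug_img, ion_imgs[["reference"]]) else drug_img

    stage <- "gate"
    cells <- apply_thresholds(cells, config$thresholds)
    cells <- assign_phenotypes(cells, config$rules)
    cells$is_endothelial <- positivity(cells, "CD31")

    stage <- "classify_cells"
    if (!"tissue_class" %in% names(cells)) {
      if (is.null(truth)) stop("cells carry no tissue_class and no truth labels are available for training")
      ct <- truth$cell_truth
      lab <- ct$tissue_class[match(cells$cell_id, ct$cell_id)]
      set.seed(split_seed(seed, "train-split"))
      idx <- unlist(lapply(split(seq_len(nrow(cells)), lab), function(i)
        sample(i, max(20, round(config$train_fraction * length(i))))))
      train <- cells[idx, ]
      train$tissue_class <- lab[idx]
      class(train) <- class(cells)
      attributes(train)$markers <- cell_markers(cells)
      cells <- classify_cell_tissue(train, cells, seed = seed)
      cell_class_accuracy <- mean(cells$tissue_class == lab)
    } else cell_class_accuracy <- NA_real_

    stage <- "register"
    reg_mode <- config$registration$mode
    if (reg_mode == "truth") {
      if (is.null(truth)) stop("registration mode 'truth' needs ground truth")
      tf <- truth$transform
      reg_report <- list(mode = "truth")
    } else {
      fixed <- representative_image_msi(ds_raw)
      moving <- representative_image_imc(cells)
      est <- estimate_transform(fixed, moving,
                                model = config$registration$model %||% "similarity",
                                metric = config$registration$metric %||% "ncc")
      tf <- est$transform
      reg_report <- est$report
    }
    corner_err <- if (!is.null(truth))
      mean_corner_error(tf, truth$transform,
                        extent = c(diff(range(cells$x_um)),
                                   diff(range(cells$y_um)))) else NA_real_
    write_affine_json(tf, file.path(out, "transform.json"))

    stage <- "vote"
    cells <- transform_cells(cells, tf, ds_raw)
    vote <- majority_vote_labels(cells, ds_raw)

    stage <- "knn"
    excl <- if (isTRUE(config$knn$exclude_analytes)) ions$mz else numeric()
    labels <- fit_predict_knn(ds_tic, vote, k = config$knn$k,
                              exclude_mz = excl)
    write_label_map(labels, file.path(out, "label_map_predicted.csv"))
    summary_cls <- class_mean_intensities(ds_raw, labels, ions)
    utils::write.csv(summary_cls, file.path(out, "class_mean_intensities.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "correlate"
    correlations <- lapply(config$correlation_markers, function(m) {
      mp <- rasterize_marker(cells, ds_raw, marker = m)
      pearson_map_correlation(mp, drug_img)
    })
    names(correlations) <- config$correlation_markers

    stage <- "enrich"
    # densities are only meaningful where IMC actually covered the section:
    # restrict the stromal region to the bounding box of the mapped cells
    inb <- cells$in_bounds
    imc_cov <- matrix(FALSE, ds_raw$ny, ds_raw$nx)
    imc_cov[(min(cells$iy[inb]):max(cells$iy[inb])) + 1L,
            (min(cells$ix[inb]):max(cells$ix[inb])) + 1L] <- TRUE
    stroma <- msi_grid_matrix(ds_raw, rep(1, nrow(ds_raw$coords)))
    stroma <- !is.na(stroma) & labels$labels == "connective" & imc_cov
    strat <- stratify_high_low(drug_img, region_mask = stroma)
    enrich <- phenotype_enrichment(cells, strat$high, strat$low, ds_raw,
                                   phenotypes = c("M2_macrophage",
                                                  "endothelial"))

    stage <- "quantify"
    fr_pred <- drug_fraction_by_class(drug_img, labels)
    fr_truth <- if (!is.null(truth))
      drug_fraction_by_class(drug_img, truth$label_map) else NULL
    pixel_accuracy <- if (!is.null(truth)) {
      tm <- truth$label_map$labels
      mean((labels$labels == tm)[tm != "unassigned"])
    } else NA_real_

    summary <- list(
      seed = seed,
      n_pixels = nrow(ds_raw$intensities),
      n_tissue_pixels = sum(ds_raw$tissue_mask),
      n_cells = nrow(cells),
      cell_class_accuracy = cell_class_accuracy,
      registration = reg_report[c("similarity_metric_value", "converged",
                                  "metric", "mode")],
      mean_corner_error_um = corner_err,
      pixel_label_accuracy = pixel_accuracy,
      label_counts = as.list(table(factor(labels$labels,
                                          levels = all_labels()))),
      correlations = lapply(correlations, function(x)
        list(r = x$r, n_pixels = x$n_pixels)),
      enrichment = stats::setNames(
        lapply(seq_len(nrow(enrich)), function(i)
          list(fold = enrich$fold[i], density_high = enrich$density_high[i],
               density_low = enrich$density_low[i])),
        enrich$phenotype),
      drug_fraction_predicted_labels =
        stats::setNames(as.list(fr_pred$fraction), fr_pred$class),
      drug_fraction_truth_labels = if (!is.null(fr_truth))
        stats::setNames(as.list(fr_truth$fraction), fr_truth$class) else NULL,
      planted_tumor_drug_fraction = if (!is.null(truth))
        truth$planted_tumor_drug_fraction else NULL)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    writeLines(c(log_lines, paste("cells:", nrow(cells)),
                 paste("k:", config$knn$k)), file.path(out, "pipeline.log"))
    invisible(summary)
  }, error = on_fail)
}
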