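# Synthetic paired MSI + IMC data with full ground truth. The generator
# emulates the statistical structure the analysis pipeline assumes: a
# contiguous tumor/connective/necrosis mosaic inside a tissue blob on an
# anisotropic 50 x 75 um pixel grid, class-dependent peak templates with
# multiplicative log-normal noise, a drug ion coupled to the local M2
# macrophage density (so high-drug stroma is genuinely macrophage-enriched),
# Poisson cell point patterns with phenotype-dependent marker expression,
# and a known similarity transform separating the IMC and MSI frames.

synthetic_phenotypes <- function() c(
  "tumor_cell", "fibroblast", "endothelial", "debris",
  "macrophage", "M1_macrophage", "M2_macrophage", "immature_monocyte",
  "dendritic_cell", "neutrophil")

#' Default per-phenotype marker expression models
#'
#' Log-normal marker intensities: a meanlog per (phenotype, marker) on three
#' tiers (negative ~0.5, moderate ~8, positive ~30 counts), a common sdlog,
#' and additive per-tissue-class meanlog shifts on context markers (ECM and
#' damage channels) reflecting local environment spillover.
#'
#' @return list with `meanlog` (phenotype x marker), `sdlog`, `class_shift`
#'   (class x marker)
#' @export
default_marker_models <- function() {
  mk <- panel_markers()
  ph <- synthetic_phenotypes()
  neg <- log(0.5); mod <- log(8); pos <- log(30)
  m <- matrix(neg, length(ph), length(mk), dimnames = list(ph, mk))
  set_pos <- function(p, markers, level = pos) m[p, markers] <<- level
  set_pos("tumor_cell", c("ECadherin", "EpCAM", "PanCK"))
  set_pos("tumor_cell", c("Ki67", "pS6"), mod)
  set_pos("fibroblast", c("aSMA", "Vimentin", "Collagen1", "Desmin"))
  set_pos("endothelial", "CD31")
  set_pos("endothelial", c("Vimentin", "aSMA"), mod)
  set_pos("debris", "CleavedCaspase3")
  set_pos("debris", "GLUT1", mod)
  set_pos("macrophage", c("CD45", "CD11b", "F480", "CD68"))
  set_pos("M1_macrophage", c("CD45", "CD11b", "F480", "CD68", "MHCII"))
  set_pos("M2_macrophage", c("CD45", "CD11b", "F480", "CD68", "CD163",
                             "CD206", "Arg1"))
  set_pos("immature_monocyte", c("CD45", "CD11b", "F480", "Ly6G"))
  set_pos("immature_monocyte", "CD68", mod)
  set_pos("dendritic_cell", c("CD45", "CD11b", "CD68", "CD11c", "MHCII"))
  set_pos("dendritic_cell", "F480", mod)
  set_pos("neutrophil", c("CD45", "CD11b", "Ly6G"))
  shift <- matrix(0, 3, length(mk), dimnames = list(tissue_classes(), mk))
  shift["connective", "Collagen1"] <- 1.2
  shift["connective", "Vimentin"] <- 0.6
  shift["necrosis", "CleavedCaspase3"] <- 2.2
  shift["necrosis", "GLUT1"] <- 1.2
  shift["tumor", "EpCAM"] <- 0.7
  shift["tumor", "ECadherin"] <- 0.7
  list(meanlog = m, sdlog = 0.4, class_shift = shift)
}

default_peak_templates <- function(n_peaks = 36) {
  j <- seq_len(n_peaks)
  base <- 40 + 60 * abs(sin(1.7 * j))
  # each class over-expresses a third of the peaks 4-fold; overall signal
  # level also differs by class (necrotic tissue ionizes poorly), which
  # gives the TIC image the mosaic contrast real sections show
  level <- c(1, 0.75, 0.35)
  t(vapply(1:3, function(cl)
    level[cl] * base * (1 + 3 * (j %% 3 == cl - 1)), base))
}

#' Synthetic dataset configuration
#'
#' All generator parameters in one validated object. Defaults define the
#' benchmark conditions: a 128 x 128 grid of 50 x 75 um pixels, tissue class
#' priors (0.5, 0.3, 0.2) over tumor/connective/necrosis, 40 Voronoi
#' regions, cell densities 800/600/60 cells/mm^2, a drug ion whose
#' noise-free intensity is baseline(class) + m2_coef x local planted M2
#' density, high-drug stromal zones with 5.1-fold M2 and 1.8-fold
#' endothelial density, and an IMC frame displaced from the MSI frame by a
#' similarity transform (10 deg rotation, 1.05 scale, (250, -150) um
#' translation). Drug coefficients are solved so the planted tumor
#' compartment holds about 45% of total drug signal.
#'
#' @param grid_nx,grid_ny grid dimensions (>= 8)
#' @param pixel_size_x_um,pixel_size_y_um pixel pitch (um)
#' @param n_tissue_regions number of Voronoi regions in the tissue
#' @param class_priors probability vector over (tumor, connective, necrosis)
#' @param peak_templates 3 x n matrix of per-class mean peak intensities
#' @param peak_mz m/z positions of the template peaks
#' @param background_factor intensity multiplier for background pixels
#' @param peak_sdlog log-normal dispersion of tissue peaks
#' @param drug_mz,metabolite_mz,reference_mz analyte ion positions (Th)
#' @param drug_baseline per-class noise-free drug baseline
#' @param drug_m2_coef drug increment per unit planted M2 density (mm^2/cell)
#' @param drug_sdlog log-normal dispersion of the drug/metabolite ions
#' @param metabolite_frac metabolite level as a fraction of the drug level
#' @param reference_mean,reference_sdlog structural-analogue reference ion
#' @param cell_density_per_class cells per mm^2 per tissue class
#' @param phenotype_mix_per_class named list: per class, probability vector
#'   over phenotypes
#' @param zone_multipliers per-phenotype density multipliers in high/low
#'   drug stroma zones
#' @param marker_models see [default_marker_models()]
#' @param marker_sdlog override for the marker log-sd (NULL = model value)
#' @param transform_truth list(rotation_deg, scale, translation_um)
#' @param imc_roi_fraction central fraction of the grid covered by the IMC
#'   acquisition region (per axis)
#' @param tissue_ellipse list(a, b, angle_deg) as fractions of the grid
#' @param seed master seed; all sub-generators derive their streams from it
#' @return a validated `synth_config`
#' @export
synth_config <- function(grid_nx = 128, grid_ny = 128,
                         pixel_size_x_um = 50, pixel_size_y_um = 75,
                         n_tissue_regions = 40,
                         class_priors = c(tumor = 0.5, connective = 0.3,
                                          necrosis = 0.2),
                         peak_templates = default_peak_templates(),
                         peak_mz = NULL,
                         background_factor = 0.005,
                         peak_sdlog = 0.3,
                         drug_mz = 507.25, metabolite_mz = 478.26,
                         reference_mz = 520.2492,
                         drug_baseline = c(tumor = 6, connective = 2.303,
                                           necrosis = 0.5),
                         drug_m2_coef = 0.08,
                         drug_sdlog = 0.25,
                         metabolite_frac = 0.4,
                         reference_mean = 10, reference_sdlog = 0.1,
                         cell_density_per_class = c(tumor = 800,
                                                    connective = 600,
                                                    necrosis = 60),
                         phenotype_mix_per_class = NULL,
                         zone_multipliers = list(
                           M2_macrophage = c(high = 5.1, low = 1),
                           endothelial = c(high = 1.8, low = 1)),
                         marker_models = default_marker_models(),
                         marker_sdlog = NULL,
                         transform_truth = list(rotation_deg = 10,
                                                scale = 1.05,
                                                translation_um = c(250, -150)),
                         imc_roi_fraction = 0.7,
                         tissue_ellipse = list(a = 0.42, b = 0.44,
                                               angle_deg = 20),
                         seed = 1) {
  if (is.null(phenotype_mix_per_class)) {
    z <- stats::setNames(numeric(length(synthetic_phenotypes())),
                         synthetic_phenotypes())
    mixes <- list(
      tumor = replace(z, c("tumor_cell", "macrophage", "M2_macrophage",
                           "M1_macrophage", "dendritic_cell", "neutrophil",
                           "immature_monocyte", "fibroblast", "endothelial"),
                      c(0.78, 0.05, 0.04, 0.03, 0.02, 0.02, 0.02, 0.02, 0.02)),
      connective = replace(z, c("fibroblast", "endothelial", "macrophage",
                                "M2_macrophage", "M1_macrophage",
                                "immature_monocyte", "dendritic_cell",
                                "neutrophil", "tumor_cell"),
                           c(0.40, 0.08, 0.12, 0.10, 0.06, 0.04, 0.05, 0.05, 0.10)),
      necrosis = replace(z, c("debris", "macrophage", "neutrophil",
                              "M2_macrophage", "tumor_cell"),
                         c(0.70, 0.10, 0.10, 0.05, 0.05)))
    phenotype_mix_per_class <- mixes
  }
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              pixel_size_x_um = pixel_size_x_um,
              pixel_size_y_um = pixel_size_y_um,
              n_tissue_regions = as.integer(n_tissue_regions),
              class_priors = class_priors, peak_templates = peak_templates,
              peak_mz = peak_mz %||% default_peak_mz(ncol(peak_templates)),
              background_factor = background_factor, peak_sdlog = peak_sdlog,
              drug_mz = drug_mz, metabolite_mz = metabolite_mz,
              reference_mz = reference_mz, drug_baseline = drug_baseline,
              drug_m2_coef = drug_m2_coef, drug_sdlog = drug_sdlog,
              metabolite_frac = metabolite_frac,
              reference_mean = reference_mean,
              reference_sdlog = reference_sdlog,
              cell_density_per_class = cell_density_per_class,
              phenotype_mix_per_class = phenotype_mix_per_class,
              zone_multipliers = zone_multipliers,
              marker_models = marker_models,
              marker_sdlog = marker_sdlog %||% marker_models$sdlog,
              transform_truth = transform_truth,
              imc_roi_fraction = imc_roi_fraction,
              tissue_ellipse = tissue_ellipse, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

default_peak_mz <- function(n) {
  mz <- seq(255, 995, length.out = n)
  specials <- c(478.26, 507.25, 520.2492)
  for (s in specials) mz[abs(mz - s) < 0.5] <- mz[abs(mz - s) < 0.5] + 1
  mz
}

validate_synth_config <- function(cfg) {
  if (cfg$grid_nx < 8 || cfg$grid_ny < 8) stop("grid dimensions must be >= 8")
  if (cfg$pixel_size_x_um <= 0 || cfg$pixel_size_y_um <= 0)
    stop("pixel sizes must be positive")
  if (abs(sum(cfg$class_priors) - 1) > 1e-9)
    stop("class_priors must sum to 1")
  if (any(cfg$class_priors < 0)) stop("class_priors must be nonnegative")
  if (any(cfg$cell_density_per_class < 0)) stop("cell densities must be nonnegative")
  if (cfg$peak_sdlog < 0 || cfg$drug_sdlog < 0 || cfg$marker_sdlog < 0 ||
      cfg$reference_sdlog < 0)
    stop("noise dispersions must be nonnegative")
  for (cl in names(cfg$phenotype_mix_per_class)) {
    mix <- cfg$phenotype_mix_per_class[[cl]]
    if (abs(sum(mix) - 1) > 1e-9)
      stop("phenotype mix for class '", cl, "' must sum to 1")
    if (any(mix < 0)) stop("phenotype mixes must be nonnegative")
  }
  if (cfg$transform_truth$scale == 0) stop("truth transform is not invertible")
  invisible(cfg)
}

#' Ground-truth similarity transform of a configuration (IMC -> MSI)
#' @param config a `synth_config`
#' @return an `affine2d`
#' @export
truth_transform <- function(config) {
  with(config$transform_truth,
       similarity2d(rotation_deg, scale, translation_um))
}

# pixel centre coordinates (um) in column-major grid order [iy + 1 + ny*ix]
grid_centers <- function(config) {
  nx <- config$grid_nx; ny <- config$grid_ny
  ix <- rep(seq_len(nx) - 1L, each = ny)
  iy <- rep(seq_len(ny) - 1L, times = nx)
  list(ix = ix, iy = iy,
       x = (ix + 0.5) * config$pixel_size_x_um,
       y = (iy + 0.5) * config$pixel_size_y_um)
}

# greedy largest-first assignment of region areas to classes, tracking the
# remaining pixel deficit of each class so realized fractions hug the priors
greedy_assign <- function(areas, priors) {
  target <- priors * sum(areas)
  assigned <- numeric(length(priors))
  out <- integer(length(areas))
  for (i in order(areas, decreasing = TRUE)) {
    deficit <- target - assigned
    cl <- which.max(deficit)
    out[i] <- cl
    assigned[cl] <- assigned[cl] + areas[i]
  }
  out
}

#' Generate the ground-truth tissue label map
#'
#' A rotated tissue ellipse inside the grid is partitioned into Voronoi
#' regions of seeded points; regions are assigned tissue classes by a greedy
#' largest-first rule that keeps realized pixel fractions close to the
#' priors. Connective regions are additionally split into high/low drug
#' zones of roughly equal area (attribute `"zone"`). Deterministic given the
#' configuration seed.
#'
#' @param config a `synth_config`
#' @return a `tissue_label_map` with attributes `"region"` and `"zone"`
#' @export
generate_tissue_map <- function(config) {
  validate_synth_config(config)
  set.seed(split_seed(config$seed, "tissue-map"))
  g <- grid_centers(config)
  W <- config$grid_nx * config$pixel_size_x_um
  H <- config$grid_ny * config$pixel_size_y_um
  el <- config$tissue_ellipse
  phi <- el$angle_deg * pi / 180
  dx <- g$x - 0.5 * W; dy <- g$y - 0.5 * H
  u <- (dx * cos(phi) + dy * sin(phi)) / (el$a * W)
  v <- (-dx * sin(phi) + dy * cos(phi)) / (el$b * H)
  tissue <- u^2 + v^2 <= 1

  n_seed <- config$n_tissue_regions
  sx <- numeric(0); sy <- numeric(0)
  while (length(sx) < n_seed) {
    cx <- stats::runif(4 * n_seed, 0, W); cy <- stats::runif(4 * n_seed, 0, H)
    du <- ((cx - 0.5 * W) * cos(phi) + (cy - 0.5 * H) * sin(phi)) / (el$a * W)
    dv <- (-(cx - 0.5 * W) * sin(phi) + (cy - 0.5 * H) * cos(phi)) / (el$b * H)
    ok <- du^2 + dv^2 <= 1
    sx <- c(sx, cx[ok]); sy <- c(sy, cy[ok])
  }
  sx <- sx[seq_len(n_seed)]; sy <- sy[seq_len(n_seed)]

  region <- rep(NA_integer_, length(g$x))
  ti <- which(tissue)
  d2 <- outer(g$x[ti], sx, "-")^2 + outer(g$y[ti], sy, "-")^2
  region[ti] <- max.col(-d2, ties.method = "first")

  areas <- tabulate(region[ti], nbins = n_seed)
  cls_of_region <- greedy_assign(areas, config$class_priors)
  labels <- rep("background", length(g$x))
  labels[ti] <- tissue_classes()[cls_of_region[region[ti]]]

  # Stromal drug zones are balanced by their area INSIDE the IMC acquisition
  # rectangle: the acquisition regions are placed to contain both high and
  # low drug content, so the analyzed stroma should hold both in comparable
  # amounts regardless of how the mosaic is clipped.
  conn_regions <- which(cls_of_region == 2L)
  zone_of_region <- rep(NA_character_, n_seed)
  if (length(conn_regions)) {
    r <- config$imc_roi_fraction
    in_roi <- abs(g$x - 0.5 * W) <= 0.5 * r * W &
      abs(g$y - 0.5 * H) <= 0.5 * r * H
    roi_areas <- vapply(conn_regions, function(rg)
      sum(region[ti] == rg & in_roi[ti]), 0L)
    # weight clipped-away regions by a nominal fraction of their total area
    # so they still receive zones, without dominating the in-ROI balance
    eff <- roi_areas + 0.05 * areas[conn_regions]
    z <- greedy_assign(eff, c(0.5, 0.5))
    zone_of_region[conn_regions] <- c("high", "low")[z]
  }
  zone <- rep(NA_character_, length(g$x))
  zone[ti] <- zone_of_region[region[ti]]

  ny <- config$grid_ny; nx <- config$grid_nx
  out <- tissue_label_map(matrix(labels, ny, nx))
  attr(out, "region") <- matrix(region, ny, nx)
  attr(out, "zone") <- matrix(zone, ny, nx)
  out
}

# planted (expected) M2 density in cells/mm^2 at every grid pixel
planted_m2_density <- function(label_map, config) {
  lab <- as.vector(label_map$labels)
  zone <- as.vector(attr(label_map, "zone") %||%
                      matrix(NA_character_, label_map$ny, label_map$nx))
  dens <- numeric(length(lab))
  zm <- config$zone_multipliers$M2_macrophage %||% c(high = 1, low = 1)
  for (cl in tissue_classes()) {
    sel <- lab == cl
    base <- config$cell_density_per_class[[cl]] *
      config$phenotype_mix_per_class[[cl]][["M2_macrophage"]]
    mult <- rep(1, sum(sel))
    if (cl == "connective") {
      mult <- ifelse(zone[sel] == "high", zm[["high"]], zm[["low"]])
      mult[is.na(mult)] <- 1
    }
    dens[sel] <- base * mult
  }
  dens
}

# mean-preserving multiplicative log-normal noise
lognoise <- function(v, sdlog) {
  if (sdlog == 0) return(v)
  v * exp(stats::rnorm(length(v), -sdlog^2 / 2, sdlog))
}

#' Generate the MSI dataset for a tissue map
#'
#' Per-pixel peak intensities follow the class template under multiplicative
#' log-normal noise; the drug ion is baseline(class) + m2_coef x planted M2
#' density (so drug co-varies with stroma and macrophage density), the
#' metabolite tracks the drug at `metabolite_frac`, and the reference ion is
#' uniform over tissue. Background pixels carry `background_factor` times
#' the mean tissue signal. The noise-free analyte fields and the planted
#' tumor drug fraction are attached as attribute `"truth_local"`.
#'
#' @param label_map a `tissue_label_map` from [generate_tissue_map()]
#' @param config a `synth_config`
#' @return an `msi_dataset` whose `tissue_mask` is the truth tissue mask
#' @export
generate_msi <- function(label_map, config) {
  validate_synth_config(config)
  set.seed(split_seed(config$seed, "msi"))
  lab <- as.vector(label_map$labels)
  present <- setdiff(unique(lab), "background")
  tpl <- config$peak_templates
  rownames(tpl) <- rownames(tpl) %||% tissue_classes()
  missing_tpl <- setdiff(present, rownames(tpl))
  if (length(missing_tpl))
    stop("no peak template for class(es): ", paste(missing_tpl, collapse = ", "))

  n <- length(lab); np <- ncol(tpl)
  nf_peaks <- matrix(config$background_factor * rep(colMeans(tpl), each = n), n, np)
  for (cl in present) nf_peaks[lab == cl, ] <- rep(tpl[cl, ], each = sum(lab == cl))

  tissue <- lab != "background"
  m2 <- planted_m2_density(label_map, config)
  nf_drug <- numeric(n)
  for (cl in present)
    nf_drug[lab == cl] <- config$drug_baseline[[cl]] +
      config$drug_m2_coef * m2[lab == cl]
  nf_drug[!tissue] <- config$background_factor * mean(nf_drug[tissue])
  nf_met <- config$metabolite_frac * nf_drug
  nf_ref <- ifelse(tissue, config$reference_mean,
                   config$background_factor * config$reference_mean)

  peaks <- matrix(lognoise(as.vector(nf_peaks), config$peak_sdlog), n, np)
  drug <- lognoise(nf_drug, config$drug_sdlog)
  met <- lognoise(nf_met, config$drug_sdlog)
  ref <- lognoise(nf_ref, config$reference_sdlog)

  mz_all <- c(config$peak_mz, config$metabolite_mz, config$drug_mz,
              config$reference_mz)
  ord <- order(mz_all)
  ints <- cbind(peaks, met, drug, ref)[, ord, drop = FALSE]

  g <- grid_centers(config)
  ds <- msi_dataset(mz = mz_all[ord], intensities = ints,
                    coords = cbind(g$ix, g$iy),
                    nx = config$grid_nx, ny = config$grid_ny,
                    pixel_size = c(config$pixel_size_x_um,
                                   config$pixel_size_y_um),
                    tissue_mask = tissue)
  tum_frac <- sum(nf_drug[lab == "tumor"]) / sum(nf_drug[tissue])
  attr(ds, "truth_local") <- list(
    noise_free_drug = nf_drug, noise_free_metabolite = nf_met,
    noise_free_reference = nf_ref, m2_density = m2,
    planted_tumor_drug_fraction = tum_frac)
  ds
}

#' Generate the IMC cell table for a tissue map
#'
#' Cells arise from independent Poisson point processes per (class,
#' phenotype) with the configured densities; high-drug stromal zones
#' multiply the M2 and endothelial densities by the planted folds. Marker
#' intensities are log-normal around the phenotype model plus the class
#' context shift. Cells are placed in the MSI frame (inside the IMC
#' acquisition rectangle) and emitted in IMC coordinates through the inverse
#' truth transform; the per-cell truth labels and MSI positions are attached
#' as attribute `"truth"`.
#'
#' @param label_map a `tissue_label_map`
#' @param config a `synth_config`
#' @return a `cell_table`; attribute `"truth"` holds per-cell truth,
#'   attribute `"imc_roi"` the acquisition rectangle (um, MSI frame)
#' @export
generate_cells <- function(label_map, config) {
  validate_synth_config(config)
  tf <- truth_transform(config)
  tf_inv <- affine_invert(tf)
  set.seed(split_seed(config$seed, "cells"))
  g <- grid_centers(config)
  lab <- as.vector(label_map$labels)
  zone <- as.vector(attr(label_map, "zone") %||%
                      matrix(NA_character_, label_map$ny, label_map$nx))
  W <- config$grid_nx * config$pixel_size_x_um
  H <- config$grid_ny * config$pixel_size_y_um
  r <- config$imc_roi_fraction
  roi <- c(xmin = 0.5 * (1 - r) * W, xmax = 0.5 * (1 + r) * W,
           ymin = 0.5 * (1 - r) * H, ymax = 0.5 * (1 + r) * H)
  in_roi <- g$x >= roi["xmin"] & g$x <= roi["xmax"] &
    g$y >= roi["ymin"] & g$y <= roi["ymax"]
  pa <- config$pixel_size_x_um * config$pixel_size_y_um / 1e6

  px <- numeric(0); py <- numeric(0)
  phen <- character(0); tcls <- character(0)
  for (cl in tissue_classes()) {
    sel <- which(lab == cl & in_roi)
    if (!length(sel)) next
    mix <- config$phenotype_mix_per_class[[cl]]
    for (p in synthetic_phenotypes()) {
      if (mix[[p]] == 0) next
      lambda <- rep(config$cell_density_per_class[[cl]] * mix[[p]] * pa,
                    length(sel))
      if (cl == "connective" && !is.null(config$zone_multipliers[[p]])) {
        zm <- config$zone_multipliers[[p]]
        lambda <- lambda * ifelse(zone[sel] == "high", zm[["high"]], zm[["low"]])
      }
      counts <- stats::rpois(length(sel), lambda)
      tot <- sum(counts)
      if (!tot) next
      at <- rep(sel, counts)
      px <- c(px, g$x[at] + stats::runif(tot, -0.5, 0.5) * config$pixel_size_x_um)
      py <- c(py, g$y[at] + stats::runif(tot, -0.5, 0.5) * config$pixel_size_y_um)
      phen <- c(phen, rep(p, tot)); tcls <- c(tcls, rep(cl, tot))
    }
  }
  n <- length(px)
  if (!n) stop("no cells generated; check densities and ROI")

  mm <- config$marker_models
  mk <- colnames(mm$meanlog)
  meanlog <- mm$meanlog[phen, , drop = FALSE] +
    mm$class_shift[tcls, , drop = FALSE]
  ints <- matrix(exp(stats::rnorm(n * length(mk), as.vector(meanlog),
                                  config$marker_sdlog)), n, length(mk))
  colnames(ints) <- mk
  area <- exp(stats::rnorm(n, log(80), 0.3))

  imc <- affine_apply(tf_inv, cbind(px, py))
  df <- data.frame(cell_id = seq_len(n), x_um = imc[, 1], y_um = imc[, 2],
                   area_um2 = area)
  df <- cbind(df, as.data.frame(ints))
  cells <- cell_table(df, markers = mk)
  attr(cells, "truth") <- data.frame(cell_id = seq_len(n),
                                     tissue_class = tcls, phenotype = phen,
                                     x_msi_um = px, y_msi_um = py)
  attr(cells, "imc_roi") <- roi
  cells
}

#' Generate a complete paired dataset with ground truth
#'
#' Runs the tissue-map, MSI and cell generators under one seed and bundles
#' the ground truth a validation needs: the label map (with stroma zones),
#' the truth transform, the planted tumor drug fraction, the planted
#' enrichment folds, the noise-free drug/M2 correlation, and per-cell truth
#' labels.
#'
#' @param config a `synth_config`
#' @return a `synth_bundle`: list(msi, cells, truth, config)
#' @export
generate_dataset <- function(config = synth_config()) {
  label_map <- generate_tissue_map(config)
  msi <- generate_msi(label_map, config)
  cells <- generate_cells(label_map, config)
  tl <- attr(msi, "truth_local")
  lab <- as.vector(label_map$labels)
  tissue <- lab != "background"
  folds <- vapply(config$zone_multipliers, function(zm) zm[["high"]] / zm[["low"]], 0)
  corr <- stats::cor(tl$noise_free_drug[tissue], tl$m2_density[tissue])
  truth <- list(label_map = label_map,
                transform = truth_transform(config),
                planted_tumor_drug_fraction = tl$planted_tumor_drug_fraction,
                planted_enrichment_folds = folds,
                planted_marker_ion_correlations = c(M2_density = corr),
                cell_truth = attr(cells, "truth"),
                imc_roi = attr(cells, "imc_roi"),
                noise_free_drug = tl$noise_free_drug,
                m2_density = tl$m2_density)
  structure(list(msi = msi, cells = cells, truth = truth, config = config),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("<synth_bundle> seed ", x$config$seed, ": ", sep = "")
  cat(nrow(x$msi$intensities), " MSI pixels, ", nrow(x$cells), " cells, ",
      "planted tumor drug fraction ",
      round(x$truth$planted_tumor_drug_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Simulate a pixel-aligned marker map / ion image pair with planted
#' Pearson correlation
#'
#' Draws bivariate-normal fields with correlation `rho` and maps the second
#' onto a positive ion-intensity scale (an affine map, which leaves Pearson
#' correlation untouched).
#'
#' @param nx,ny grid size
#' @param rho planted correlation
#' @param seed RNG seed
#' @param pixel_size pixel pitch (um)
#' @return list(marker_map = matrix, ion = `ion_image`, rho = rho)
#' @export
simulate_correlated_maps <- function(nx = 100, ny = 100, rho = 0.7, seed = 1,
                                     pixel_size = c(50, 75)) {
  stopifnot(abs(rho) <= 1)
  set.seed(split_seed(seed, "correlated-maps"))
  z <- stats::rnorm(nx * ny)
  e <- stats::rnorm(nx * ny)
  b <- rho * z + sqrt(1 - rho^2) * e
  marker <- matrix(5 + z, ny, nx)
  ion <- ion_image(matrix(20 + 4 * b - 4 * min(b), ny, nx),
                   pixel_size = pixel_size)
  list(marker_map = marker, ion = ion, rho = rho)
}
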