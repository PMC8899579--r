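#' MSI dataset container
#'
#' Peak-reduced mass spectrometry imaging data on a rectangular pixel grid.
#' Pixels are indexed 0-based; pixel `(ix, iy)` covers the half-open physical
#' rectangle `[ix * px, (ix + 1) * px) x [iy * py, (iy + 1) * py)` micrometres,
#' the convention also used when cells are binned into pixels. The default
#' pixel pitch is the anisotropic DESI raster of 50 um (x) by 75 um (y).
#'
#' @param mz strictly increasing numeric vector of peak centroids (Th)
#' @param intensities nonnegative matrix, one row per pixel, one column per peak
#' @param coords integer matrix (n_pixels x 2) of 0-based (ix, iy)
#' @param nx,ny grid dimensions; defaults to the coordinate extent
#' @param pixel_size numeric length-2, micrometres per pixel in x and y
#' @param tissue_mask optional logical vector per pixel (TRUE = tissue)
#' @param normalization one of "raw", "tic", "reference_ion"
#' @return an object of class `msi_dataset`
#' @export
msi_dataset <- function(mz, intensities, coords, nx = NULL, ny = NULL,
                        pixel_size = c(50, 75), tissue_mask = NULL,
                        normalization = "raw") {
  intensities <- as.matrix(intensities)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (length(mz) != ncol(intensities))
    stop("length(mz) must equal ncol(intensities)")
  if (is.unsorted(mz, strictly = TRUE))
    stop("mz axis must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  if (nrow(coords) != nrow(intensities))
    stop("one coordinate pair per pixel required")
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stop("duplicate pixel coordinates")
  nx <- nx %||% (max(coords[, 1]) + 1L)
  ny <- ny %||% (max(coords[, 2]) + 1L)
  if (any(coords[, 1] < 0 | coords[, 1] >= nx | coords[, 2] < 0 | coords[, 2] >= ny))
    stop("pixel coordinates outside grid")
  tissue_mask <- tissue_mask %||% rep(TRUE, nrow(coords))
  stopifnot(length(tissue_mask) == nrow(coords))
  structure(list(mz = as.numeric(mz), intensities = intensities,
                 coords = coords, nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = as.numeric(pixel_size),
                 tissue_mask = as.logical(tissue_mask),
                 normalization = normalization),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("<msi_dataset> ", nrow(x$intensities), " pixels on a ", x$nx, "x", x$ny,
      " grid (", x$pixel_size[1], "x", x$pixel_size[2], " um), ",
      length(x$mz), " peaks, m/z ", round(min(x$mz), 2), "-",
      round(max(x$mz), 2), ", normalization: ", x$normalization, "\n", sep = "")
  cat("  tissue pixels: ", sum(x$tissue_mask), "\n", sep = "")
  invisible(x)
}

#' Total ion current per pixel
#' @param ds an `msi_dataset`
#' @return numeric vector, one value per pixel
#' @export
msi_tic <- function(ds) rowSums(ds$intensities)

#' Spread a per-pixel vector onto the grid as an ny x nx matrix
#' @param ds an `msi_dataset`
#' @param values numeric vector aligned with the dataset's pixel rows
#' @return matrix with NA at grid positions not present in the dataset
#' @export
msi_grid_matrix <- function(ds, values) {
  stopifnot(length(values) == nrow(ds$coords))
  m <- matrix(NA_real_, ds$ny, ds$nx)
  m[ds$coords[, 2] + 1L + ds$ny * ds$coords[, 1]] <- values
  m
}

# per-pixel row index for grid position (ix, iy); NA if absent
msi_row_index <- function(ds, ix, iy) {
  key <- paste(ds$coords[, 1], ds$coords[, 2])
  match(paste(ix, iy), key)
}

#' Background detection by k-means on spectral summaries
#'
#' Clusters pixels on standardized log-intensity features (log TIC plus the
#' highest-variance peaks; the log compresses between-class tissue contrast so
#' the dominant split is signal vs no-signal) and flags low-signal cluster(s)
#' as background: any cluster whose mean TIC is below the brightest cluster's
#' mean TIC divided by `min_contrast`.
#' If no cluster is that dim (an essentially uniform section) the whole grid
#' is kept as tissue.
#'
#' @param ds an `msi_dataset`
#' @param k number of clusters (>= 2)
#' @param n_top_peaks how many high-variance peaks join TIC as features
#' @param min_contrast minimum bright/dim mean-TIC ratio for a background call
#' @param seed RNG seed for k-means initialization
#' @return the dataset with an updated `tissue_mask` (background = FALSE);
#'   attribute `"background"` carries the background mask
#' @export
detect_background <- function(ds, k = 2, n_top_peaks = 10, min_contrast = 5,
                              seed = 1) {
  stopifnot(inherits(ds, "msi_dataset"), nrow(ds$intensities) > k)
  tic <- msi_tic(ds)
  if (all(tic == 0)) stop("no tissue detected: dataset is all zero")
  v <- apply(ds$intensities, 2, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_peaks, ncol(ds$intensities)))]
  feats <- log1p(cbind(tic, ds$intensities[, top, drop = FALSE]))
  sds <- apply(feats, 2, stats::sd)
  feats <- scale(feats, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  feats[, sds == 0] <- 0
  set.seed(split_seed(seed, "kmeans-background"))
  km <- stats::kmeans(feats, centers = k, nstart = 5, iter.max = 50)
  mean_tic <- tapply(tic, km$cluster, mean)
  bg_clusters <- as.integer(names(mean_tic))[mean_tic < max(mean_tic) / min_contrast]
  background <- km$cluster %in% bg_clusters
  ds$tissue_mask <- !background
  attr(ds, "background") <- background
  ds
}

#' Total ion current normalization
#'
#' Divides each pixel's peak vector by its TIC so normalized intensities sum
#' to one per pixel; idempotent. Tissue pixels with zero TIC cannot be
#' normalized and are dropped from the tissue mask with a warning.
#'
#' @param ds an `msi_dataset`
#' @return the normalized dataset (`normalization = "tic"`)
#' @export
tic_normalize <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  tic <- msi_tic(ds)
  zero_tissue <- ds$tissue_mask & tic == 0
  if (any(zero_tissue)) {
    warning(sum(zero_tissue), " tissue pixel(s) with zero TIC dropped from tissue mask")
    ds$tissue_mask[zero_tissue] <- FALSE
  }
  pos <- tic > 0
  ds$intensities[pos, ] <- ds$intensities[pos, , drop = FALSE] / tic[pos]
  ds$normalization <- "tic"
  ds
}

#' Ion image extraction
#'
#' Sums, per pixel, the intensities of all peaks within `mz_tol` of
#' `mz_center` (inclusive window), e.g. the reference window m/z
#' 520.2492 +/- 0.005 used for structural-analogue normalization.
#'
#' @param ds an `msi_dataset`
#' @param mz_center window centre (Th)
#' @param mz_tol half-width of the window (Th)
#' @return an `ion_image`
#' @export
extract_ion_image <- function(ds, mz_center, mz_tol) {
  stopifnot(inherits(ds, "msi_dataset"), mz_tol >= 0)
  sel <- abs(ds$mz - mz_center) <= mz_tol
  if (!any(sel)) {
    near <- ds$mz[order(abs(ds$mz - mz_center))][seq_len(min(3, length(ds$mz)))]
    stop("no peaks within ", mz_tol, " of m/z ", mz_center,
         "; nearest peaks: ", paste(round(near, 4), collapse = ", "))
  }
  vals <- rowSums(ds$intensities[, sel, drop = FALSE])
  ion_image(values = msi_grid_matrix(ds, vals),
            valid = msi_grid_matrix(ds, as.numeric(ds$tissue_mask)) == 1,
            mz_center = mz_center, mz_tol = mz_tol,
            normalization = ds$normalization, pixel_size = ds$pixel_size)
}

#' Ion image container
#'
#' @param values ny x nx matrix of nonnegative intensities (NA where missing)
#' @param valid logical ny x nx matrix of usable pixels
#' @param mz_center,mz_tol the extraction window (Th)
#' @param normalization one of "raw", "tic", "reference_ion"
#' @param pixel_size micrometres per pixel (x, y)
#' @return an object of class `ion_image`
#' @export
ion_image <- function(values, valid = NULL, mz_center = NA_real_,
                      mz_tol = NA_real_, normalization = "raw",
                      pixel_size = c(50, 75)) {
  stopifnot(is.matrix(values))
  valid <- valid %||% !is.na(values)
  valid[is.na(valid)] <- FALSE
  if (any(values[valid] < 0, na.rm = TRUE)) stop("ion image values must be nonnegative")
  structure(list(values = values, valid = valid, mz_center = mz_center,
                 mz_tol = mz_tol, normalization = normalization,
                 pixel_size = as.numeric(pixel_size)),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat("<ion_image> m/z ", x$mz_center, " +/- ", x$mz_tol, ", ",
      ncol(x$values), "x", nrow(x$values), " px, ", sum(x$valid),
      " valid, normalization: ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Reference-ion (structural analogue) normalization
#'
#' Per-pixel ratio of a drug ion image to a reference ion image, the scheme
#' used to correct section-to-section ionization efficiency with a structural
#' analogue. Pixels where the reference falls below `min_ref` are marked
#' invalid rather than producing unstable ratios.
#'
#' @param drug,ref `ion_image`s on the same grid
#' @param min_ref reference floor; default: 1st percentile of positive
#'   reference intensities
#' @return an `ion_image` tagged `reference_ion`
#' @export
normalize_to_reference <- function(drug, ref, min_ref = NULL) {
  stopifnot(inherits(drug, "ion_image"), inherits(ref, "ion_image"))
  if (!identical(dim(drug$values), dim(ref$values)))
    stop("drug and reference images are on different grids")
  rv <- ref$values
  if (is.null(min_ref)) {
    pos <- rv[ref$valid & !is.na(rv) & rv > 0]
    min_ref <- if (length(pos)) stats::quantile(pos, 0.01, names = FALSE) else .Machine$double.eps
  }
  valid <- drug$valid & ref$valid & !is.na(rv) & rv > 0 & rv >= min_ref
  out <- matrix(NA_real_, nrow(rv), ncol(rv))
  out[valid] <- drug$values[valid] / rv[valid]
  ion_image(out, valid = valid, mz_center = drug$mz_center,
            mz_tol = drug$mz_tol, normalization = "reference_ion",
            pixel_size = drug$pixel_size)
}

#' Export an ion image as CSV (ix, iy, value, valid)
#' @param img an `ion_image`
#' @param path output file
#' @export
write_ion_image_csv <- function(img, path) {
  ny <- nrow(img$values); nx <- ncol(img$values)
  utils::write.csv(data.frame(ix = rep(seq_len(nx) - 1L, each = ny),
                              iy = rep(seq_len(ny) - 1L, times = nx),
                              value = as.vector(img$values),
                              valid = as.vector(img$valid)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
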