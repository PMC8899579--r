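# Cross-modality analysis: pixel-aligned marker maps, Pearson correlation
# with ion images, ROI selection over heterogeneous drug fields, and
# high-vs-low drug phenotype enrichment.

pixel_area_mm2 <- function(pixel_size) prod(pixel_size) / 1e6

#' Rasterize a marker or phenotype onto the MSI grid
#'
#' Aggregates the cells assigned to each pixel: mean (or sum) marker
#' intensity, or phenotype-positive cell count. Pixels containing no cells
#' are missing (NA) — a marker map is undefined where nothing was measured.
#'
#' @param cells a `cell_table` with pixel indices (see [transform_cells()])
#' @param ds the `msi_dataset` providing the grid
#' @param marker marker name (mutually exclusive with `phenotype`)
#' @param phenotype phenotype name: counts cells whose `is_<phenotype>` flag
#'   (or primary label) matches
#' @param agg `"mean"` or `"sum"` for marker maps
#' @return an ny x nx numeric matrix
#' @export
rasterize_marker <- function(cells, ds, marker = NULL, phenotype = NULL,
                             agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  stopifnot(inherits(ds, "msi_dataset"), xor(is.null(marker), is.null(phenotype)))
  if (!all(c("ix", "iy") %in% names(cells)))
    stop("cells lack pixel indices; run transform_cells first")
  keep <- if ("in_bounds" %in% names(cells)) cells$in_bounds else rep(TRUE, nrow(cells))
  if (!is.null(marker)) {
    marker <- normalize_marker_names(marker)
    if (!marker %in% names(cells)) stop("unknown marker: ", marker)
    w <- cells[[marker]]
  } else {
    col <- paste0("is_", phenotype)
    w <- if (col %in% names(cells)) as.numeric(cells[[col]])
         else if ("phenotype" %in% names(cells)) as.numeric(cells$phenotype == phenotype)
         else stop("no phenotype assignment found; run assign_phenotypes first")
  }
  m <- matrix(NA_real_, ds$ny, ds$nx)
  if (any(keep)) {
    pid <- cells$iy[keep] + 1L + ds$ny * cells$ix[keep]
    sums <- tapply(w[keep], pid, sum)
    ids <- as.integer(names(sums))
    if (!is.null(phenotype)) {
      m[ids] <- sums                      # counts
    } else if (agg == "sum") {
      m[ids] <- sums
    } else {
      m[ids] <- sums / as.numeric(table(pid))
    }
  }
  m
}

#' Pearson correlation between a marker map and an ion image
#'
#' Computed over jointly valid pixels (both finite, inside `mask` and the
#' ion image's valid mask). Zero variance in either map yields a missing
#' value with a reason rather than an error.
#'
#' @param map ny x nx numeric matrix (e.g. from [rasterize_marker()])
#' @param ion an `ion_image` on the same grid
#' @param mask optional logical matrix restricting the pixels
#' @return list with `r`, `n_pixels`, `method`, and `reason` when `r` is NA
#' @export
pearson_map_correlation <- function(map, ion, mask = NULL) {
  stopifnot(is.matrix(map), inherits(ion, "ion_image"),
            identical(dim(map), dim(ion$values)))
  ok <- is.finite(map) & is.finite(ion$values) & ion$valid
  if (!is.null(mask)) ok <- ok & mask
  n <- sum(ok)
  if (n < 3) stop("need >= 3 jointly valid pixels; got ", n)
  a <- map[ok]; b <- ion$values[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, n_pixels = n, method = "pearson",
                reason = "zero variance"))
  }
  list(r = stats::cor(a, b), n_pixels = n, method = "pearson")
}

#' Select the most heterogeneous rectangular ROI of a drug image
#'
#' Scans candidate rectangles on a stride grid and returns the one
#' maximizing the within-ROI interquartile range of drug intensity — the
#' criterion used to place IMC acquisition regions over areas containing
#' both high and low drug content. Ties go to the first candidate in
#' row-major scan order.
#'
#' @param drug an `ion_image`
#' @param roi_size_px c(width, height) in pixels
#' @param stride_px scan stride; default a quarter of the ROI size
#' @return list with 0-based `ix0`, `iy0`, `width`, `height`, `score`,
#'   and logical matrix `mask`
#' @export
select_heterogeneous_roi <- function(drug, roi_size_px,
                                     stride_px = NULL) {
  stopifnot(inherits(drug, "ion_image"), length(roi_size_px) == 2)
  nx <- ncol(drug$values); ny <- nrow(drug$values)
  w <- roi_size_px[1]; h <- roi_size_px[2]
  if (w > nx || h > ny) stop("ROI (", w, "x", h, ") larger than grid (",
                             nx, "x", ny, ")")
  stride_px <- stride_px %||% pmax(1L, floor(c(w, h) / 4))
  if (length(stride_px) == 1) stride_px <- rep(stride_px, 2)
  xs <- unique(c(seq(0L, nx - w, by = stride_px[1]), nx - w))
  ys <- unique(c(seq(0L, ny - h, by = stride_px[2]), ny - h))
  best <- NULL
  for (y0 in ys) for (x0 in xs) {
    v <- drug$values[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
    ok <- drug$valid[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] & is.finite(v)
    score <- if (sum(ok) >= 4) stats::IQR(v[ok]) else -Inf
    if (is.null(best) || score > best$score) {
      best <- list(ix0 = x0, iy0 = y0, width = w, height = h, score = score)
    }
  }
  mask <- matrix(FALSE, ny, nx)
  mask[(best$iy0 + 1):(best$iy0 + h), (best$ix0 + 1):(best$ix0 + w)] <- TRUE
  best$mask <- mask
  best
}

#' Split a region into high- and low-drug pixels
#'
#' Median split by default (parameter-free); `q` selects another quantile,
#' e.g. `q = 0.75` makes "high" the top quartile. The two masks are disjoint
#' and their union is exactly the valid region.
#'
#' @param drug an `ion_image`
#' @param region_mask optional logical matrix; default: all valid pixels
#' @param q quantile for the threshold (default 0.5 = median)
#' @return list with logical matrices `high`, `low` and the `threshold`
#' @export
stratify_high_low <- function(drug, region_mask = NULL, q = 0.5) {
  stopifnot(inherits(drug, "ion_image"))
  region <- drug$valid & is.finite(drug$values)
  if (!is.null(region_mask)) region <- region & region_mask
  v <- drug$values[region]
  if (length(v) < 2) stop("region has fewer than 2 valid pixels")
  if (diff(range(v)) == 0) stop("no contrast: drug intensity constant in region")
  thr <- stats::quantile(v, q, names = FALSE)
  high <- region & drug$values > thr
  high[is.na(high)] <- FALSE
  low <- region & !high
  list(high = high, low = low, threshold = thr)
}

#' Phenotype enrichment in high- vs low-drug areas
#'
#' Densities are phenotype-positive cells per mm^2 of mask area (nominal
#' pixel area, 50 x 75 um^2 = 3750 um^2 by default); the fold is
#' density_high / density_low. A zero low-density yields `fold = NA` with
#' `fold_infinite = TRUE` rather than a number.
#'
#' @param cells a gated `cell_table` with pixel indices
#' @param mask_high,mask_low disjoint logical matrices over the grid
#' @param ds the `msi_dataset` providing grid geometry
#' @param phenotypes phenotype names to evaluate
#' @return an `enrichment_report` data frame: phenotype, counts, densities
#'   (cells/mm^2), `fold`, `fold_infinite`
#' @export
phenotype_enrichment <- function(cells, mask_high, mask_low, ds,
                                 phenotypes = c("M2_macrophage")) {
  stopifnot(inherits(ds, "msi_dataset"),
            identical(dim(mask_high), dim(mask_low)))
  if (any(mask_high & mask_low)) stop("high/low masks overlap")
  if (!all(c("ix", "iy") %in% names(cells)))
    stop("cells lack pixel indices; run transform_cells first")
  keep <- if ("in_bounds" %in% names(cells)) cells$in_bounds else rep(TRUE, nrow(cells))
  pid <- rep(NA_integer_, nrow(cells))
  pid[keep] <- cells$iy[keep] + 1L + ds$ny * cells$ix[keep]
  in_high <- keep & mask_high[pid]
  in_low <- keep & mask_low[pid]
  in_high[is.na(in_high)] <- FALSE; in_low[is.na(in_low)] <- FALSE
  area_high <- sum(mask_high) * pixel_area_mm2(ds$pixel_size)
  area_low <- sum(mask_low) * pixel_area_mm2(ds$pixel_size)
  rows <- lapply(phenotypes, function(p) {
    col <- paste0("is_", p)
    flag <- if (col %in% names(cells)) cells[[col]]
            else if ("phenotype" %in% names(cells)) cells$phenotype == p
            else stop("no phenotype assignment found for ", p)
    nh <- sum(flag & in_high); nl <- sum(flag & in_low)
    dh <- if (area_high > 0) nh / area_high else NA_real_
    dl <- if (area_low > 0) nl / area_low else NA_real_
    inf <- isTRUE(dl == 0)
    data.frame(phenotype = p, n_high = nh, n_low = nl,
               density_high = dh, density_low = dl,
               fold = if (inf || is.na(dl)) NA_real_ else dh / dl,
               fold_infinite = inf)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_report", "data.frame")
  out
}
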