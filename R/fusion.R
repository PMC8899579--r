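# Label transfer from classified cells to MSI pixels: strict majority vote
# per pixel, then a k-nearest-neighbor classifier over pixel spectra extends
# the labels (plus a background class) to the entire dataset.

#' Majority-vote pixel labels from co-registered cells
#'
#' A pixel is labeled class c iff strictly more than 50% of the cells mapped
#' into it carry class c; pixels with no cells, or with no strict majority
#' (e.g. an exact 50/50 split), stay `unassigned`.
#'
#' @param cells a `cell_table` with `tissue_class`, `ix`, `iy` and
#'   `in_bounds` columns (see [transform_cells()])
#' @param ds the `msi_dataset` providing the grid
#' @return a partial `tissue_label_map` (provenance `vote`)
#' @export
majority_vote_labels <- function(cells, ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  need <- c("tissue_class", "ix", "iy")
  if (!all(need %in% names(cells)))
    stop("cells must carry tissue_class and pixel indices; run transform_cells first")
  keep <- if ("in_bounds" %in% names(cells)) cells$in_bounds else rep(TRUE, nrow(cells))
  labels <- matrix("unassigned", ds$ny, ds$nx)
  prov <- matrix("none", ds$ny, ds$nx)
  if (any(keep)) {
    pid <- cells$iy[keep] + 1L + ds$ny * cells$ix[keep]
    cls <- factor(cells$tissue_class[keep], levels = tissue_classes())
    counts <- table(pid, cls)
    tot <- rowSums(counts)
    win <- max.col(counts, ties.method = "first")
    frac <- counts[cbind(seq_len(nrow(counts)), win)] / tot
    has_majority <- frac > 0.5
    ids <- as.integer(rownames(counts))[has_majority]
    labels[ids] <- tissue_classes()[win[has_majority]]
    prov[ids] <- "vote"
  }
  tissue_label_map(labels, prov)
}

#' kNN classification of all MSI pixels from vote-labeled pixels
#'
#' Fits a k-nearest-neighbor classifier (default k = 30) on all pixels
#' carrying a vote label, together with a background class drawn from the
#' k-means background, and predicts every pixel of the dataset — including
#' regions never covered by IMC. Features are the pixel's (TIC-normalized)
#' peak intensities, standardized per peak; analyte ions (drug, metabolite,
#' reference) are excluded by default so tissue classification is not driven
#' by the quantity being measured. Ties are broken by smallest aggregate
#' neighbor distance, then by the fixed class order
#' tumor < connective < necrosis < background.
#'
#' @param ds an `msi_dataset` (TIC-normalize first for comparable spectra)
#' @param partial a vote-labeled `tissue_label_map`
#' @param k number of neighbors
#' @param background_mask logical per-pixel vector of background training
#'   pixels; default: the complement of the dataset's tissue mask
#' @param exclude_mz numeric m/z values whose peaks (within `exclude_tol`)
#'   are dropped from the feature set
#' @param exclude_tol half-window (Th) for `exclude_mz`
#' @param cap_background cap background training pixels at the median
#'   per-class tissue count to avoid class imbalance (deterministic,
#'   evenly-spaced subsample)
#' @return a complete `tissue_label_map` (provenance `knn`, background
#'   training pixels `kmeans_background`)
#' @export
fit_predict_knn <- function(ds, partial, k = 30, background_mask = NULL,
                            exclude_mz = numeric(), exclude_tol = 0.3,
                            cap_background = TRUE) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(partial, "tissue_label_map"))
  if (partial$nx != ds$nx || partial$ny != ds$ny)
    stop("label map and dataset grids differ")
  background_mask <- background_mask %||% !ds$tissue_mask

  keep_peak <- rep(TRUE, length(ds$mz))
  for (m in exclude_mz) keep_peak <- keep_peak & abs(ds$mz - m) > exclude_tol
  X <- ds$intensities[, keep_peak, drop = FALSE]
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  ok <- sdv > 0
  X <- sweep(sweep(X[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")

  # per-pixel row in the dataset for each grid position
  grid_row <- rep(NA_integer_, ds$ny * ds$nx)
  grid_row[ds$coords[, 2] + 1L + ds$ny * ds$coords[, 1]] <- seq_len(nrow(ds$coords))

  lab_vec <- as.vector(partial$labels)[!is.na(grid_row)]
  rows <- grid_row[!is.na(grid_row)]
  train_rows <- rows[lab_vec %in% tissue_classes()]
  train_lab <- lab_vec[lab_vec %in% tissue_classes()]
  bg_rows <- which(background_mask)
  bg_rows <- setdiff(bg_rows, train_rows)
  if (cap_background && length(train_lab)) {
    cap <- stats::median(table(train_lab))
    if (length(bg_rows) > cap) {
      bg_rows <- bg_rows[round(seq(1, length(bg_rows), length.out = cap))]
    }
  }
  classes <- c(tissue_classes(), "background")
  tr <- c(train_rows, bg_rows)
  trl <- c(train_lab, rep("background", length(bg_rows)))
  if (length(unique(trl)) < 2) stop("need >= 2 classes among training labels")
  if (length(tr) < k)
    stop("only ", length(tr), " labeled training pixels for k = ", k,
         "; use a smaller k")

  Xtr <- X[tr, , drop = FALSE]
  trf <- match(trl, classes)
  n <- nrow(X)
  pred <- integer(n)
  sq_tr <- rowSums(Xtr^2)
  chunk <- max(1L, floor(2e7 / length(tr)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Xi <- X[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), sq_tr, "+") - 2 * Xi %*% t(Xtr)
    for (j in seq_len(nrow(d2))) {
      nb <- order(d2[j, ])[seq_len(k)]
      cl <- trf[nb]
      cnt <- tabulate(cl, nbins = length(classes))
      best <- which(cnt == max(cnt))
      if (length(best) > 1) {
        agg <- vapply(best, function(ci) sum(d2[j, nb[cl == ci]]), 0)
        best <- best[agg == min(agg)]
      }
      pred[s + j - 1L] <- best[1]
    }
  }

  labels <- matrix("unassigned", ds$ny, ds$nx)
  prov <- matrix("none", ds$ny, ds$nx)
  gidx <- ds$coords[, 2] + 1L + ds$ny * ds$coords[, 1]
  labels[gidx] <- classes[pred]
  prov[gidx] <- "knn"
  prov[gidx[bg_rows]] <- ifelse(labels[gidx[bg_rows]] == "background",
                                "kmeans_background", "knn")
  tissue_label_map(labels, prov)
}

#' Per-class mean ion intensities
#'
#' Arithmetic mean of selected ion images over the pixels of each tissue
#' class — the per-compartment summary of ions of interest.
#'
#' @param ds an `msi_dataset`
#' @param labels a `tissue_label_map` on the same grid
#' @param ions data frame with columns `name`, `mz`, `tol`
#' @param classes classes to summarize (default: the tissue classes)
#' @return a `class_summary` data frame: `class`, `pixel_count`, one mean
#'   column per ion (NA for empty classes)
#' @export
class_mean_intensities <- function(ds, labels, ions,
                                   classes = tissue_classes()) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(labels, "tissue_label_map"))
  ions <- as.data.frame(ions)
  stopifnot(all(c("name", "mz", "tol") %in% names(ions)))
  lab_at_pixel <- labels$labels[ds$coords[, 2] + 1L + ds$ny * ds$coords[, 1]]
  out <- data.frame(class = classes,
                    pixel_count = vapply(classes, function(cl)
                      sum(lab_at_pixel == cl), 0L))
  for (i in seq_len(nrow(ions))) {
    vals <- rowSums(ds$intensities[
      , abs(ds$mz - ions$mz[i]) <= ions$tol[i], drop = FALSE])
    out[[paste0("mean_", ions$name[i])]] <- vapply(classes, function(cl) {
      sel <- lab_at_pixel == cl
      if (!any(sel)) NA_real_ else mean(vals[sel])
    }, 0)
  }
  class(out) <- c("class_summary", "data.frame")
  out
}
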