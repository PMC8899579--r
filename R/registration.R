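# Intensity-based co-registration of the two modalities. Everything is done
# in physical micrometres: the anisotropic MSI raster (50 x 75 um) and the
# IMC cell raster are both resampled to a common isotropic working grid
# before any similarity metric is evaluated.

#' Spatial image: a matrix with physical pixel geometry
#'
#' @param values ny x nx matrix
#' @param pixel_size um per pixel (x, y)
#' @param origin physical position (um) of the grid's (0, 0) pixel corner
#' @return a `spat_image`
#' @export
spat_image <- function(values, pixel_size, origin = c(0, 0)) {
  stopifnot(is.matrix(values), length(pixel_size) == 2)
  structure(list(values = values, pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin)), class = "spat_image")
}

#' @export
print.spat_image <- function(x, ...) {
  cat("<spat_image> ", ncol(x$values), "x", nrow(x$values), " px at ",
      x$pixel_size[1], "x", x$pixel_size[2], " um\n", sep = "")
  invisible(x)
}

#' Representative image of an MSI dataset
#'
#' The TIC image rescaled to [0, 1]; the standard structural snapshot used as
#' the fixed image in co-registration. A constant image is flagged
#' low-contrast via attribute `"low_contrast"`.
#'
#' @param ds an `msi_dataset`
#' @return a `spat_image` on the MSI grid
#' @export
representative_image_msi <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"), nrow(ds$intensities) > 0)
  m <- msi_grid_matrix(ds, msi_tic(ds))
  mx <- max(m, na.rm = TRUE)
  low <- FALSE
  if (mx > 0) m <- m / mx
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) < 1e-12) low <- TRUE
  out <- spat_image(m, ds$pixel_size)
  attr(out, "low_contrast") <- low
  out
}

#' Representative image of an IMC cell table
#'
#' Bins cells onto an isotropic raster in the IMC frame and sums a channel
#' per bin (default: total marker intensity), then smooths lightly and
#' rescales to [0, 1]. This density-like raster is the moving image in
#' co-registration.
#'
#' @param cells a `cell_table`
#' @param channel a marker name, or `"total"` for the summed panel, or
#'   `"count"` for plain cell counts
#' @param pitch_um raster pitch in um
#' @param smooth_sigma_px Gaussian smoothing sigma in raster pixels
#' @param extent_um optional c(xmax, ymax) raster extent; default fits cells
#' @return a `spat_image` in the IMC frame
#' @export
representative_image_imc <- function(cells, channel = "total", pitch_um = 25,
                                     smooth_sigma_px = 1.5, extent_um = NULL) {
  stopifnot(inherits(cells, "cell_table"), nrow(cells) > 0)
  if (channel == "total") {
    w <- rowSums(as.data.frame(cells)[cell_markers(cells)])
  } else if (channel == "count") {
    w <- rep(1, nrow(cells))
  } else {
    ch <- normalize_marker_names(channel)
    if (!ch %in% names(cells)) stop("unknown channel: ", channel)
    w <- cells[[ch]]
  }
  x0 <- min(cells$x_um); y0 <- min(cells$y_um)
  if (!is.null(extent_um)) { x0 <- 0; y0 <- 0 }
  xmax <- if (is.null(extent_um)) max(cells$x_um) else extent_um[1]
  ymax <- if (is.null(extent_um)) max(cells$y_um) else extent_um[2]
  nx <- max(1L, ceiling((xmax - x0) / pitch_um))
  ny <- max(1L, ceiling((ymax - y0) / pitch_um))
  ix <- pmin(pmax(floor((cells$x_um - x0) / pitch_um), 0), nx - 1)
  iy <- pmin(pmax(floor((cells$y_um - y0) / pitch_um), 0), ny - 1)
  m <- matrix(0, ny, nx)
  idx <- iy + 1L + ny * ix
  agg <- tapply(w, idx, sum)
  m[as.integer(names(agg))] <- agg
  # bins far from any cell were never imaged, not truly dark: mask them so
  # partial IMC coverage does not bias downstream similarity metrics
  occ <- matrix(0, ny, nx)
  cnt <- tapply(rep(1, length(idx)), idx, sum)
  occ[as.integer(names(cnt))] <- cnt
  occ <- gaussian_blur(occ, max(3, 2 * smooth_sigma_px))
  m <- gaussian_blur(m, smooth_sigma_px)
  valid <- occ > 0.02 * mean(occ[occ > 0])
  if (max(m[valid]) > 0) m <- m / max(m[valid])
  m[!valid] <- NA_real_
  spat_image(m, c(pitch_um, pitch_um), origin = c(x0, y0))
}

# resample a spat_image to an isotropic pitch (bilinear)
resample_isotropic <- function(img, pitch_um) {
  ext_x <- ncol(img$values) * img$pixel_size[1]
  ext_y <- nrow(img$values) * img$pixel_size[2]
  nx <- max(2L, round(ext_x / pitch_um)); ny <- max(2L, round(ext_y / pitch_um))
  cx <- img$origin[1] + (seq_len(nx) - 0.5) * pitch_um
  cy <- img$origin[2] + (seq_len(ny) - 0.5) * pitch_um
  pts <- cbind(rep(cx, each = ny), rep(cy, times = nx))
  v <- bilinear_sample(img$values, pts[, 1], pts[, 2], img$pixel_size, img$origin)
  spat_image(matrix(v, ny, nx), c(pitch_um, pitch_um), img$origin)
}

metric_ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 50) return(-1)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(-1)
  stats::cor(a[ok], b[ok])
}

metric_mi <- function(a, b, bins = 32) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 50) return(-1)
  a <- a[ok]; b <- b[ok]
  if (diff(range(a)) == 0 || diff(range(b)) == 0) return(-1)
  ia <- pmin(bins, 1L + floor((a - min(a)) / diff(range(a)) * bins))
  ib <- pmin(bins, 1L + floor((b - min(b)) / diff(range(b)) * bins))
  pj <- matrix(tabulate((ia - 1L) * bins + ib, nbins = bins * bins),
               bins, bins) / length(ia)
  pa <- colSums(pj); pb <- rowSums(pj)   # pj[ib, ia]
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pb, pa)[nz]))
}

params_to_tf <- function(theta, model) {
  if (model == "similarity") {
    similarity2d(theta[1], exp(theta[2]), theta[3:4])
  } else {
    affine2d(matrix(theta[1:4], 2, 2), theta[5:6])
  }
}

tf_to_params <- function(tf, model) {
  if (model == "similarity") {
    sc <- sqrt(abs(det(tf$A)))
    c(atan2(tf$A[2, 1], tf$A[1, 1]) * 180 / pi, log(sc), tf$t)
  } else {
    c(as.numeric(tf$A), tf$t)
  }
}

#' Estimate the IMC-to-MSI transform from representative images
#'
#' Multi-resolution intensity-based registration. Both images are resampled
#' to isotropic working grids; at each level the transform parameters are
#' optimized (Nelder-Mead) to maximize a similarity metric between the fixed
#' image and the warped moving image. Normalized cross-correlation drives
#' the coarse-to-fine pyramid (it has the widest, smoothest capture range),
#' and with the default `metric = "mi"` the finest level is then refined
#' under 32-bin mutual information, which tolerates the nonlinear intensity
#' relationship between a TIC image and a cell-intensity raster. A
#' deterministic coarse sweep over rotations and translation offsets guards
#' against local optima, and the isotropic scale is kept within
#' `scale_bounds` (serial sections of the same block cannot differ much in
#' scale). The whole procedure is deterministic given `init`.
#'
#' @param fixed `spat_image` in the target (MSI) frame
#' @param moving `spat_image` in the source (IMC) frame
#' @param model `"similarity"` (rigid + isotropic scale) or `"affine"`
#' @param metric `"mi"` (NCC pyramid + MI refinement) or `"ncc"` (NCC only)
#' @param init optional initial `affine2d`; default: intensity-centroid
#'   alignment
#' @param levels_um working pitches (um) from coarse to fine
#' @param maxit Nelder-Mead iteration cap per level
#' @param rotation_sweep_deg rotations tried at the coarsest level
#' @param scale_bounds admissible isotropic scale range
#' @return list with `transform` (an `affine2d`) and `report`
#'   (metric value, convergence flag, per-level trace)
#' @export
estimate_transform <- function(fixed, moving, model = c("similarity", "affine"),
                               metric = c("mi", "ncc"), init = NULL,
                               levels_um = c(200, 100, 50, 25), maxit = 300,
                               rotation_sweep_deg = seq(-20, 20, by = 10),
                               scale_bounds = c(0.8, 1.25)) {
  model <- match.arg(model); metric <- match.arg(metric)
  for (img in list(fixed, moving)) {
    if (stats::sd(img$values, na.rm = TRUE) == 0)
      stop("no contrast: constant image cannot be registered")
  }
  centroid <- function(img) {
    v <- img$values; v[!is.finite(v)] <- 0
    tot <- sum(v)
    cx <- img$origin[1] + (sum(colSums(v) * (seq_len(ncol(v)) - 0.5)) / tot) * img$pixel_size[1]
    cy <- img$origin[2] + (sum(rowSums(v) * (seq_len(nrow(v)) - 0.5)) / tot) * img$pixel_size[2]
    c(cx, cy)
  }
  if (is.null(init)) {
    init <- similarity2d(0, 1, centroid(fixed) - centroid(moving))
  }
  theta <- tf_to_params(init, "similarity")
  log_sb <- log(scale_bounds)

  objective <- function(theta_mod, lev, model_now, mfun) {
    if (model_now == "similarity" &&
        (theta_mod[2] < log_sb[1] || theta_mod[2] > log_sb[2])) return(-2)
    inv <- affine_invert(params_to_tf(theta_mod, model_now))
    src <- affine_apply(inv, lev$pts)
    mvv <- bilinear_sample(lev$mv$values, src[, 1], src[, 2],
                           lev$mv$pixel_size, lev$mv$origin)
    mfun(lev$fv, mvv)
  }

  level_images <- lapply(levels_um, function(L) {
    fx <- resample_isotropic(fixed, L)
    mv <- resample_isotropic(moving, L)
    fx$values <- gaussian_blur(fx$values, 0.5)
    mv$values <- gaussian_blur(mv$values, 0.5)
    nxf <- ncol(fx$values); nyf <- nrow(fx$values)
    cx <- fx$origin[1] + (seq_len(nxf) - 0.5) * fx$pixel_size[1]
    cy <- fx$origin[2] + (seq_len(nyf) - 0.5) * fx$pixel_size[2]
    list(fx = fx, mv = mv, pts = cbind(rep(cx, each = nyf), rep(cy, times = nxf)),
         fv = as.vector(fx$values))
  })

  trace <- numeric(0)
  converged <- TRUE
  for (li in seq_along(levels_um)) {
    L <- levels_um[li]
    lev <- level_images[[li]]
    if (li == 1) {
      # dense deterministic search over rotation x translation at the
      # coarsest level: the centroid init can be several hundred um off
      # when the moving image covers only part of the section, and the
      # coarse NCC landscape is too flat for a local optimizer to recover
      offs <- seq(-5 * L, 5 * L, by = L)
      grid <- expand.grid(r = rotation_sweep_deg, dx = offs, dy = offs)
      scores <- vapply(seq_len(nrow(grid)), function(i) {
        objective(c(grid$r[i], theta[2],
                    theta[3] + grid$dx[i], theta[4] + grid$dy[i]),
                  lev, "similarity", metric_ncc)
      }, 0)
      b <- which.max(scores)
      theta <- c(grid$r[b], theta[2],
                 theta[3] + grid$dx[b], theta[4] + grid$dy[b])
    }
    model_now <- if (model == "affine" && li == length(levels_um)) "affine" else "similarity"
    if (model_now == "affine" && length(theta) == 4)
      theta <- tf_to_params(params_to_tf(theta, "similarity"), "affine")
    parscale <- if (model_now == "similarity") c(2, 0.02, L, L) else
      c(rep(0.05, 4), L, L)
    opt <- stats::optim(theta, objective, lev = lev,
                        model_now = model_now, mfun = metric_ncc,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1,
                                       maxit = if (L > 60) min(maxit, 150) else maxit,
                                       parscale = parscale, reltol = 1e-8))
    if (opt$convergence != 0) converged <- FALSE
    # guard against divergence: keep the previous parameters if they score
    # at least as well at this level
    prev <- objective(theta, lev, model_now, metric_ncc)
    if (prev >= opt$value) {
      trace <- c(trace, prev)
    } else {
      theta <- opt$par
      trace <- c(trace, opt$value)
    }
  }
  if (metric == "mi") {
    lev <- level_images[[length(levels_um)]]
    # MI is histogram-based: half the samples carry essentially the same
    # joint distribution at a quarter of the cost
    sub <- seq(1, length(lev$fv), by = 2)
    lev$pts <- lev$pts[sub, , drop = FALSE]
    lev$fv <- lev$fv[sub]
    model_now <- if (model == "affine") "affine" else "similarity"
    parscale <- if (model_now == "similarity") c(1, 0.01, 10, 10) else
      c(rep(0.02, 4), 10, 10)
    # the MI surface is rugged at histogram scale and can hold a shallow
    # decoy maximum near the NCC solution: scan a local deterministic grid
    # first, then polish the best grid point with Nelder-Mead
    polish <- function(start, maxit_p = 250) {
      stats::optim(start, objective, lev = lev,
                   model_now = model_now, mfun = metric_mi,
                   method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = maxit_p,
                                  parscale = parscale, reltol = 1e-9))
    }
    best_val <- objective(theta, lev, model_now, metric_mi)
    if (model_now == "similarity") {
      g <- expand.grid(r = theta[1] + seq(-0.4, 0.4, 0.2),
                       dx = seq(-60, 60, 15), dy = seq(-60, 60, 15))
      sc <- vapply(seq_len(nrow(g)), function(i)
        objective(c(g$r[i], theta[2], theta[3] + g$dx[i],
                    theta[4] + g$dy[i]), lev, model_now, metric_mi), 0)
      # polish the strongest grid candidates and keep the best polished
      # optimum: decoy maxima score close to the true one at grid pitch
      for (i in order(sc, decreasing = TRUE)[1:5]) {
        opt <- polish(c(g$r[i], theta[2], theta[3] + g$dx[i],
                        theta[4] + g$dy[i]))
        if (opt$value > best_val) { theta <- opt$par; best_val <- opt$value }
      }
    } else {
      opt <- polish(theta, 400)
      if (opt$value > best_val) { theta <- opt$par; best_val <- opt$value }
    }
    trace <- c(trace, best_val)
  }
  tf <- params_to_tf(theta, if (model == "affine") "affine" else "similarity")
  tf$frame_from <- "IMC_um"; tf$frame_to <- "MSI_um"
  list(transform = tf,
       report = list(similarity_metric_value = trace[length(trace)],
                     converged = converged, metric = metric,
                     level_metric_trace = trace))
}

#' Map cells into MSI pixel space
#'
#' Applies an IMC-to-MSI transform to cell centroids and assigns each cell to
#' the MSI pixel containing it under the half-open convention: pixel
#' `(ix, iy)` covers `[ix*px, (ix+1)*px) x [iy*py, (iy+1)*py)` um. Cells
#' landing outside the grid are retained but flagged `in_bounds = FALSE`.
#' No cell is dropped.
#'
#' @param cells a `cell_table` with IMC-frame coordinates
#' @param tf an `affine2d` (IMC -> MSI)
#' @param ds the target `msi_dataset` (grid geometry)
#' @return the cell table with `x_msi_um`, `y_msi_um`, `ix`, `iy`,
#'   `in_bounds` columns
#' @export
transform_cells <- function(cells, tf, ds) {
  stopifnot(inherits(cells, "cell_table"), inherits(tf, "affine2d"),
            inherits(ds, "msi_dataset"))
  p <- affine_apply(tf, cbind(cells$x_um, cells$y_um))
  cells$x_msi_um <- p[, 1]; cells$y_msi_um <- p[, 2]
  cells$ix <- as.integer(floor(p[, 1] / ds$pixel_size[1]))
  cells$iy <- as.integer(floor(p[, 2] / ds$pixel_size[2]))
  cells$in_bounds <- cells$ix >= 0 & cells$ix < ds$nx &
    cells$iy >= 0 & cells$iy < ds$ny
  cells
}
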