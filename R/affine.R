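#' 2D affine transform between modality coordinate frames
#'
#' Maps points `p` (um) from `frame_from` to `frame_to` as `A p + t`.
#' The default frames are the IMC micrometre frame (source) and the MSI
#' micrometre frame (target).
#'
#' @param A 2x2 linear part (must be invertible)
#' @param t length-2 translation (um)
#' @param frame_from,frame_to frame tags
#' @return an `affine2d`
#' @export
affine2d <- function(A, t = c(0, 0), frame_from = "IMC_um", frame_to = "MSI_um") {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("affine transform is not invertible")
  structure(list(A = A, t = as.numeric(t), frame_from = frame_from,
                 frame_to = frame_to), class = "affine2d")
}

#' Similarity transform (rotation + isotropic scale + translation)
#' @param rotation_deg counter-clockwise rotation in degrees
#' @param scale isotropic scale factor
#' @param translation length-2 translation (um)
#' @inheritParams affine2d
#' @return an `affine2d`
#' @export
similarity2d <- function(rotation_deg = 0, scale = 1, translation = c(0, 0),
                         frame_from = "IMC_um", frame_to = "MSI_um") {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine2d(scale * R, translation, frame_from, frame_to)
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> ", x$frame_from, " -> ", x$frame_to, "\n", sep = "")
  cat("  A = [", paste(sprintf("%.6g", t(x$A)), collapse = ", "),
      "], t = (", paste(sprintf("%.6g", x$t), collapse = ", "), ") um\n", sep = "")
  invisible(x)
}

#' Apply, invert and compose affine transforms
#'
#' @param tf an `affine2d`
#' @param xy n x 2 matrix (or length-2 vector) of points in `frame_from`
#' @return `affine_apply`: n x 2 matrix of mapped points
#' @export
affine_apply <- function(tf, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  sweep(xy %*% t(tf$A), 2, tf$t, "+")
}

#' @rdname affine_apply
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  affine2d(Ai, -as.numeric(Ai %*% tf$t),
           frame_from = tf$frame_to, frame_to = tf$frame_from)
}

#' @rdname affine_apply
#' @param tf2 transform applied first (so the result is `tf` after `tf2`)
#' @export
affine_compose <- function(tf, tf2) {
  affine2d(tf$A %*% tf2$A, as.numeric(tf$A %*% tf2$t) + tf$t,
           frame_from = tf2$frame_from, frame_to = tf$frame_to)
}

#' Least-squares transform from point correspondences
#'
#' Deterministic landmark estimation: an exact least-squares affine fit, or
#' the closed-form similarity (Procrustes with scale) solution.
#'
#' @param src n x 2 source points (frame_from)
#' @param dst n x 2 matched target points (frame_to)
#' @param model `"affine"` (needs >= 3 pairs) or `"similarity"` (>= 2)
#' @inheritParams affine2d
#' @return an `affine2d`
#' @export
fit_affine_landmarks <- function(src, dst, model = c("affine", "similarity"),
                                 frame_from = "IMC_um", frame_to = "MSI_um") {
  model <- match.arg(model)
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, identical(dim(src), dim(dst)))
  n <- nrow(src)
  if (model == "affine") {
    if (n < 3) stop("affine fit needs >= 3 point pairs")
    X <- cbind(src, 1)
    beta <- qr.solve(X, dst)           # 3 x 2: rows a, b, t per output coord
    affine2d(t(beta[1:2, ]), beta[3, ], frame_from, frame_to)
  } else {
    if (n < 2) stop("similarity fit needs >= 2 point pairs")
    mu_s <- colMeans(src); mu_d <- colMeans(dst)
    sc <- sweep(src, 2, mu_s); dc <- sweep(dst, 2, mu_d)
    # complex-number closed form for rotation + scale
    zs <- complex(real = sc[, 1], imaginary = sc[, 2])
    zd <- complex(real = dc[, 1], imaginary = dc[, 2])
    a <- sum(Conj(zs) * zd) / sum(Mod(zs)^2)
    A <- matrix(c(Re(a), Im(a), -Im(a), Re(a)), 2, 2)
    affine2d(A, mu_d - as.numeric(A %*% mu_s), frame_from, frame_to)
  }
}

#' Mean corner displacement between two transforms
#'
#' Evaluates both transforms on the corners of a rectangle (um) and returns
#' the mean Euclidean discrepancy — the registration error summary.
#'
#' @param tf_a,tf_b `affine2d`s over the same source frame
#' @param corners 4 x 2 matrix of corner points; default unit square scaled
#'   by `extent`
#' @param extent width/height (um) of the default corner rectangle
#' @return mean displacement in um
#' @export
mean_corner_error <- function(tf_a, tf_b, corners = NULL, extent = c(1000, 1000)) {
  corners <- corners %||% cbind(c(0, extent[1], extent[1], 0),
                                c(0, 0, extent[2], extent[2]))
  d <- affine_apply(tf_a, corners) - affine_apply(tf_b, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Serialize / deserialize transforms as JSON
#' @param tf an `affine2d`
#' @param path JSON file path
#' @export
write_affine_json <- function(tf, path) {
  jsonlite::write_json(list(A = tf$A, t = tf$t, frame_from = tf$frame_from,
                            frame_to = tf$frame_to),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(x$A)) x$A else matrix(unlist(x$A), 2, 2, byrow = TRUE)
  affine2d(A, x$t, x$frame_from, x$frame_to)
}
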