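#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific RNG seed from a master seed
#'
#' Every stochastic component draws its seed from one master integer via a
#' named stream, so sub-generators are decoupled: changing how many draws one
#' stage consumes never perturbs another stage.
#'
#' @param seed master integer seed
#' @param stream character stream label
#' @return an integer in [1, 2^31 - 2]
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 1e9
  s <- (abs(as.numeric(seed)) %% 2147483L) * 1000 + 7
  as.integer((s * 97 + h * 7919 + 13) %% 2147483629) + 1L
}

# Bilinear interpolation of a matrix sampled on pixel centres.
# `mat` is ny x nx with pixel (ix, iy) centre at ((ix + 0.5) * px, (iy + 0.5) * py)
# in physical units relative to `origin`. Points outside the grid return NA.
bilinear_sample <- function(mat, x, y, pixel_size, origin = c(0, 0)) {
  nx <- ncol(mat); ny <- nrow(mat)
  gx <- (x - origin[1]) / pixel_size[1] - 0.5
  gy <- (y - origin[2]) / pixel_size[2] - 0.5
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  out <- rep(NA_real_, length(x))
  ok <- x0 >= 0 & x0 <= nx - 1 & y0 >= 0 & y0 <= ny - 1
  # clamp the upper neighbour so the last half pixel extrapolates flat
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  x0c <- pmax(x0, 0); y0c <- pmax(y0, 0)
  idx <- function(xx, yy) yy + 1L + nrow(mat) * xx  # column-major [y, x]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    v00 <- mat[idx(x0c[ok], y0c[ok])]
    v10 <- mat[idx(x1[ok],  y0c[ok])]
    v01 <- mat[idx(x0c[ok], y1[ok])]
    v11 <- mat[idx(x1[ok],  y1[ok])]
    fxo <- fx[ok]; fyo <- fy[ok]
    out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v10 * fxo * (1 - fyo) +
      v01 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  out
}

# Separable Gaussian blur; NAs are treated as zero weight.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  w <- !is.na(mat)
  m <- mat; m[!w] <- 0
  conv1 <- function(a, along) {
    out <- array(0, dim(a))
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      if (along == 1L) {
        src <- seq_len(nrow(a)) + sh
        keep <- src >= 1 & src <= nrow(a)
        out[keep, ] <- out[keep, , drop = FALSE] + k[i] * a[src[keep], , drop = FALSE]
      } else {
        src <- seq_len(ncol(a)) + sh
        keep <- src >= 1 & src <= ncol(a)
        out[, keep] <- out[, keep, drop = FALSE] + k[i] * a[, src[keep], drop = FALSE]
      }
    }
    out
  }
  num <- conv1(conv1(m, 1L), 2L)
  den <- conv1(conv1(w + 0, 1L), 2L)
  out <- num / pmax(den, .Machine$double.eps)
  out[den == 0] <- NA_real_
  out
}

# FNV-1a hash of a character string or raw vector, returned as 8 hex digits.
# Used for config/manifest fingerprints (not cryptographic).
fnv1a_hex <- function(x) {
  bytes <- if (is.raw(x)) as.integer(x) else utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (code in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# vectorized position-weighted content hash for (possibly large) raw vectors;
# used for file fingerprints in manifests (not cryptographic)
content_hex <- function(bytes) {
  b <- as.numeric(bytes)
  w <- (seq_along(b) - 1) %% 97 + 1
  a1 <- sum(b * w) %% 2147483629
  a2 <- sum(b * rev(w)) %% 2147483629
  sprintf("%08x%08x", as.integer(a1), as.integer(a2))
}
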