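test_that("affine transforms invert and compose correctly", {
  tf <- similarity2d(10, 1.05, c(250, -150))
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  back <- affine_apply(affine_invert(tf), affine_apply(tf, sq))
  expect_lt(max(abs(back - sq)), 1e-9)
  comp <- affine_compose(affine_invert(tf), tf)
  expect_equal(comp$A, diag(2), tolerance = 1e-12)
  expect_equal(comp$t, c(0, 0), tolerance = 1e-9)
  expect_error(affine2d(matrix(c(1, 2, 2, 4), 2, 2)), "not invertible")
})

test_that("landmark fits recover planted transforms exactly", {
  set.seed(4)
  tf <- affine2d(matrix(c(1.1, 0.1, -0.05, 0.95), 2, 2), c(30, -70))
  src <- matrix(runif(12, 0, 5000), 6, 2)
  dst <- affine_apply(tf, src)
  fit <- fit_affine_landmarks(src, dst, "affine")
  expect_equal(fit$A, tf$A, tolerance = 1e-9)
  expect_equal(fit$t, tf$t, tolerance = 1e-6)
  sim <- similarity2d(-7, 0.98, c(12, 34))
  fit2 <- fit_affine_landmarks(src, affine_apply(sim, src), "similarity")
  expect_equal(fit2$A, sim$A, tolerance = 1e-9)
  expect_error(fit_affine_landmarks(src[1:2, ], dst[1:2, ], "affine"), ">= 3")
})

test_that("transform serialization round-trips through JSON", {
  tf <- similarity2d(10, 1.05, c(250, -150))
  p <- file.path(tempdir(), "tf.json")
  write_affine_json(tf, p)
  tf2 <- read_affine_json(p)
  expect_equal(tf2$A, tf$A, tolerance = 1e-12)
  expect_equal(tf2$t, tf$t)
})

test_that("cells map to pixels under the half-open convention", {
  ds <- tiny_ds(nx = 4, ny = 3)
  df <- data.frame(cell_id = 1:3, x_um = c(125, 100, 199.999),
                   y_um = c(150, 10, 224.999), area_um2 = 80, CD45 = 1)
  cells <- cell_table(df, markers = "CD45")
  out <- transform_cells(cells, similarity2d(0, 1, c(0, 0)), ds)
  expect_equal(out$ix, c(2L, 2L, 3L))   # floor(125/50); boundary 100 -> 2
  expect_equal(out$iy, c(2L, 0L, 2L))
  expect_equal(nrow(out), nrow(cells))  # no cell dropped
  # out-of-bounds retained but flagged
  far <- cells; far$x_um <- far$x_um + 1e5
  class(far) <- class(cells); attr(far, "markers") <- "CD45"
  out2 <- transform_cells(far, similarity2d(0, 1, c(0, 0)), ds)
  expect_true(all(!out2$in_bounds))
  expect_equal(nrow(out2), 3)
})

test_that("representative images behave as declared", {
  # MSI: two-pixel TIC 2 and 4 rescales to 0.5 and 1
  ds <- msi_dataset(c(1, 2), rbind(c(1, 1), c(2, 2)), rbind(c(0, 0), c(1, 0)),
                    nx = 2, ny = 1)
  img <- representative_image_msi(ds)
  expect_equal(as.vector(img$values), c(0.5, 1))
  expect_false(attr(img, "low_contrast"))
  cds <- msi_dataset(c(1, 2), rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(1, 0)),
                     nx = 2, ny = 1)
  expect_true(attr(representative_image_msi(cds), "low_contrast"))
  # IMC: a single cell occupies one raster bin (unsmoothed)
  one <- cell_table(data.frame(cell_id = 1, x_um = 40, y_um = 60,
                               area_um2 = 80, CD45 = 3), markers = "CD45")
  r1 <- representative_image_imc(one, pitch_um = 25, smooth_sigma_px = 0)
  expect_equal(sum(r1$values > 0, na.rm = TRUE), 1)
  expect_error(representative_image_imc(one, channel = "nope"), "unknown channel")
})

test_that("doubling intensities rescales the raster linearly before norm", {
  set.seed(5)
  n <- 200
  df <- data.frame(cell_id = 1:n, x_um = runif(n, 0, 1000),
                   y_um = runif(n, 0, 1000), area_um2 = 80,
                   CD45 = runif(n, 1, 5))
  cells <- cell_table(df, markers = "CD45")
  d2 <- df; d2$CD45 <- 2 * d2$CD45
  cells2 <- cell_table(d2, markers = "CD45")
  a <- representative_image_imc(cells, smooth_sigma_px = 0)
  b <- representative_image_imc(cells2, smooth_sigma_px = 0)
  expect_equal(b$values, a$values)   # max-rescale cancels the factor 2
})

test_that("self-registration returns the identity and flags no-contrast", {
  set.seed(6)
  v <- gaussian_blur(matrix(runif(40 * 40), 40, 40), 2)
  img <- spat_image(v, c(25, 25))
  est <- estimate_transform(img, img, metric = "ncc",
                            levels_um = c(100, 50, 25),
                            rotation_sweep_deg = 0)
  err <- mean_corner_error(est$transform, similarity2d(0, 1, c(0, 0)),
                           extent = c(1000, 1000))
  expect_lt(err, 2.5)   # 0.1 px at the 25 um working pitch
  flat <- spat_image(matrix(1, 20, 20), c(25, 25))
  expect_error(estimate_transform(flat, img), "no contrast")
})

test_that("a planted similarity transform is recovered from images", {
  b <- generate_dataset(synth_config(seed = 2))
  ds <- detect_background(b$msi, seed = 2)
  est <- estimate_transform(representative_image_msi(ds),
                            representative_image_imc(b$cells))
  ex <- diff(range(b$cells$x_um)); ey <- diff(range(b$cells$y_um))
  corners <- cbind(min(b$cells$x_um) + c(0, ex, ex, 0),
                   min(b$cells$y_um) + c(0, 0, ey, ey))
  err <- mean_corner_error(est$transform, b$truth$transform, corners)
  expect_lt(err, 25)
  sc <- sqrt(det(est$transform$A))
  expect_lt(abs(sc - 1.05) / 1.05, 0.01)   # scale within 1%
})
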