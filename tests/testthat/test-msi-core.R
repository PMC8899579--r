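test_that("msi_dataset validates its invariants", {
  expect_error(msi_dataset(c(2, 1), matrix(1, 1, 2), cbind(0, 0)),
               "strictly increasing")
  expect_error(msi_dataset(c(1, 2), matrix(-1, 1, 2), cbind(0, 0)),
               "nonnegative")
  expect_error(msi_dataset(1, matrix(1, 2, 1), rbind(c(0, 0), c(0, 0))),
               "duplicate")
})

test_that("TIC normalization divides by the pixel sum and is idempotent", {
  ds <- tiny_ds(fill = function(n, p) matrix(rep(c(2, 3, 5), n), n, p,
                                             byrow = TRUE))
  dn <- tic_normalize(ds)
  expect_equal(dn$intensities[1, ], c(0.2, 0.3, 0.5))
  expect_equal(rowSums(dn$intensities), rep(1, nrow(dn$intensities)),
               tolerance = 1e-12)
  expect_equal(tic_normalize(dn)$intensities, dn$intensities)
  # global rescaling leaves the result untouched
  ds2 <- ds; ds2$intensities <- ds2$intensities * 37.5
  expect_equal(tic_normalize(ds2)$intensities, dn$intensities)
})

test_that("zero-TIC tissue pixels are dropped from the mask with a warning", {
  ds <- tiny_ds(fill = function(n, p) matrix(1, n, p))
  ds$intensities[5, ] <- 0
  expect_warning(dn <- tic_normalize(ds), "zero TIC")
  expect_false(dn$tissue_mask[5])
  expect_equal(sum(dn$tissue_mask), nrow(ds$coords) - 1)
})

test_that("ion image extraction sums peaks inside the window only", {
  set.seed(1)
  ds <- tiny_ds(mz = c(478.26, 520.2492, 520.30))
  one <- extract_ion_image(ds, 478.26, 0.005)
  expect_equal(as.vector(one$values), msi_grid_matrix(ds, ds$intensities[, 1]) |> as.vector())
  both <- extract_ion_image(ds, 520, 1)
  expect_equal(both$values[1, 1], ds$intensities[1, 2] + ds$intensities[1, 3])
  # the reference window 520.2492 +/- 0.005 takes only the matching peak
  ref <- extract_ion_image(ds, 520.2492, 0.005)
  expect_equal(ref$values[1, 1], ds$intensities[1, 2])
  expect_error(extract_ion_image(ds, 600, 0.1), "nearest peaks")
})

test_that("ion image extraction is additive over disjoint windows", {
  set.seed(2)
  ds <- tiny_ds(mz = c(300, 400, 500))
  a <- extract_ion_image(ds, 300, 10)
  b <- extract_ion_image(ds, 450, 60)
  whole <- extract_ion_image(ds, 400, 150)
  expect_equal(whole$values, a$values + b$values)
})

test_that("reference normalization guards low-reference pixels", {
  v <- matrix(c(4, 9, 2, 8), 2, 2)
  r <- matrix(c(2, 3, 0, 4), 2, 2)
  drug <- ion_image(v); ref <- ion_image(r)
  out <- normalize_to_reference(drug, ref, min_ref = 1)
  expect_equal(out$values[1, 1], 2)
  expect_false(out$valid[1, 2])       # zero reference -> invalid, not Inf
  expect_equal(out$normalization, "reference_ion")
  # identity reference
  ones <- ion_image(matrix(1, 2, 2))
  expect_equal(normalize_to_reference(drug, ones, min_ref = 1)$values, v)
  # drug == ref -> ratio one on valid pixels
  same <- normalize_to_reference(drug, drug, min_ref = 1)
  expect_true(all(same$values[same$valid] == 1))
  expect_error(normalize_to_reference(drug, ion_image(matrix(1, 3, 3))),
               "different grids")
})

test_that("k-means background detection matches a TIC-threshold oracle", {
  # two blocks: TIC ~0.3 vs ~300
  nx <- 8; ny <- 8
  coords <- cbind(rep(0:(nx - 1), each = ny), rep(0:(ny - 1), nx))
  lowblock <- coords[, 1] < 4
  set.seed(3)
  ints <- matrix(runif(nx * ny * 3, 90, 110), nx * ny, 3)
  ints[lowblock, ] <- runif(sum(lowblock) * 3, 0.05, 0.15)
  ds <- msi_dataset(c(1, 2, 3), ints, coords)
  out <- detect_background(ds)
  oracle <- msi_tic(ds) > 10          # brute-force threshold between blocks
  expect_equal(out$tissue_mask, oracle)
})

test_that("a uniform dataset yields all tissue under the contrast guard", {
  ds <- tiny_ds(fill = function(n, p) matrix(5 + runif(n * p, -0.01, 0.01), n, p),
                nx = 6, ny = 6)
  out <- detect_background(ds)
  expect_true(all(out$tissue_mask))
  expect_error(detect_background(tiny_ds(fill = function(n, p) matrix(0, n, p))),
               "no tissue")
})

test_that("background detection recovers the generator truth mask", {
  b <- generate_dataset(small_synth_config(seed = 5))
  ds <- detect_background(b$msi, seed = 5)
  truth_tissue <- as.vector(b$truth$label_map$labels) != "background"
  expect_gte(mean(ds$tissue_mask == truth_tissue), 0.99)
})
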