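vote_cells <- function(ix, iy, cls) {
  n <- length(ix)
  df <- data.frame(cell_id = seq_len(n), x_um = 0, y_um = 0, area_um2 = 80,
                   CD45 = 1)
  cells <- cell_table(df, markers = "CD45")
  cells$ix <- as.integer(ix); cells$iy <- as.integer(iy)
  cells$in_bounds <- TRUE
  cells$tissue_class <- cls
  cells
}

test_that("the vote rule is strictly greater than 50%", {
  ds <- tiny_ds(nx = 3, ny = 3)
  cells <- vote_cells(c(0, 0, 0, 1, 1), c(0, 0, 0, 0, 0),
                      c("tumor", "tumor", "connective", "tumor", "connective"))
  out <- majority_vote_labels(cells, ds)
  expect_equal(out$labels[1, 1], "tumor")        # 2/3 > 0.5
  expect_equal(out$labels[1, 2], "unassigned")   # exactly 50%
  expect_equal(out$labels[2, 2], "unassigned")   # no cells
  expect_equal(out$provenance[1, 1], "vote")
})

test_that("majority vote matches the exhaustive counting oracle", {
  set.seed(42)
  for (rep in 1:40) {
    nx <- sample(2:10, 1); ny <- sample(2:10, 1)
    n <- sample(1:60, 1)
    ix <- sample(0:(nx - 1), n, TRUE); iy <- sample(0:(ny - 1), n, TRUE)
    cls <- sample(tissue_classes(), n, TRUE)
    ds <- tiny_ds(nx = nx, ny = ny)
    got <- majority_vote_labels(vote_cells(ix, iy, cls), ds)
    expect_equal(got$labels, oracle_vote(ix, iy, cls, nx, ny))
  }
})

knn_toy <- function(n_side = 6, classes = c("tumor", "connective")) {
  # two spectrally distinct blocks plus optional background
  nx <- n_side; ny <- n_side
  coords <- cbind(rep(0:(nx - 1), each = ny), rep(0:(ny - 1), nx))
  left <- coords[, 1] < nx / 2
  set.seed(7)
  ints <- matrix(0, nx * ny, 4)
  ints[left, 1:2] <- matrix(runif(sum(left) * 2, 90, 110), ncol = 2)
  ints[!left, 3:4] <- matrix(runif(sum(!left) * 2, 90, 110), ncol = 2)
  ds <- msi_dataset(c(100, 200, 300, 400), ints, coords)
  labels <- matrix("unassigned", ny, nx)
  labels[cbind(c(1, 2), c(1, 1))] <- classes[1]
  labels[cbind(c(1, 2), c(nx, nx))] <- classes[2]
  list(ds = ds, partial = tissue_label_map(labels), left = left)
}

test_that("kNN with k = 1 reproduces training labels and fills the grid", {
  toy <- knn_toy()
  out <- fit_predict_knn(toy$ds, toy$partial, k = 1,
                         background_mask = rep(FALSE, 36))
  expect_equal(out$labels[1, 1], "tumor")
  expect_equal(out$labels[1, 6], "connective")
  expect_true(all(out$labels[, 1:3] == "tumor"))
  expect_true(all(out$labels[, 4:6] == "connective"))
  expect_true(all(out$provenance == "knn"))
})

test_that("kNN rejects degenerate training input", {
  toy <- knn_toy()
  expect_error(fit_predict_knn(toy$ds, toy$partial, k = 30,
                               background_mask = rep(FALSE, 36)),
               "smaller k")
  single <- toy$partial
  single$labels[single$labels == "connective"] <- "unassigned"
  expect_error(fit_predict_knn(toy$ds, single, k = 1,
                               background_mask = rep(FALSE, 36)),
               ">= 2 classes")
})

test_that("kNN agrees with an independent implementation when ties are absent", {
  b <- generate_dataset(small_synth_config(seed = 4))
  ds <- tic_normalize(detect_background(b$msi, seed = 4))
  cells <- b$cells
  cells$tissue_class <- b$truth$cell_truth$tissue_class
  cells <- transform_cells(cells, b$truth$transform, ds)
  vote <- majority_vote_labels(cells, ds)
  excl <- default_ions()$mz
  mine <- fit_predict_knn(ds, vote, k = 5, exclude_mz = excl)
  # rebuild the same standardized feature matrix and ask class::knn
  keep <- rep(TRUE, length(ds$mz))
  for (m in excl) keep <- keep & abs(ds$mz - m) > 0.3
  X <- ds$intensities[, keep]
  X <- scale(X)
  grid_lab <- as.vector(vote$labels)
  tr <- which(grid_lab %in% tissue_classes())
  bg <- which(!ds$tissue_mask)
  cap <- stats::median(table(grid_lab[tr]))
  if (length(bg) > cap) bg <- bg[round(seq(1, length(bg), length.out = cap))]
  trn <- c(tr, bg)
  lab <- c(grid_lab[tr], rep("background", length(bg)))
  ref <- as.character(class::knn(X[trn, ], X, factor(lab), k = 5))
  agree <- mean(as.vector(mine$labels) == ref)
  expect_gte(agree, 0.99)
})

test_that("class summaries average ions per class and conserve counts", {
  ds <- tiny_ds(mz = c(100, 200, 300),
                fill = function(n, p) matrix(rep(c(2, 4, 6), each = n), n, p))
  labels <- matrix("tumor", 3, 4); labels[, 3:4] <- "connective"
  lm <- tissue_label_map(labels)
  out <- class_mean_intensities(ds, lm, data.frame(name = "a", mz = 200, tol = 1))
  expect_equal(out$mean_a, c(4, 4, NA))
  expect_equal(sum(out$pixel_count), 12)
  # noise-free planted means are reproduced exactly
  ds2 <- ds
  ds2$intensities[as.vector(labels) == "connective", 2] <- 9
  out2 <- class_mean_intensities(ds2, lm, data.frame(name = "a", mz = 200, tol = 1))
  expect_equal(out2$mean_a[1:2], c(4, 9))
})

test_that("kNN accuracy does not decrease with template separation", {
  accs <- sapply(c(1.5, 3, 6), function(sep_fold) {
    j <- 1:36
    base <- 40 + 60 * abs(sin(1.7 * j))
    tpl <- t(sapply(1:3, function(cl)
      c(1, 0.75, 0.35)[cl] * base * (1 + (sep_fold - 1) * (j %% 3 == cl - 1))))
    b <- generate_dataset(small_synth_config(seed = 6, peak_templates = tpl))
    ds <- tic_normalize(detect_background(b$msi, seed = 6))
    cells <- b$cells
    cells$tissue_class <- b$truth$cell_truth$tissue_class
    cells <- transform_cells(cells, b$truth$transform, ds)
    vote <- majority_vote_labels(cells, ds)
    out <- fit_predict_knn(ds, vote, k = 15, exclude_mz = default_ions()$mz)
    tm <- b$truth$label_map$labels
    mean((out$labels == tm)[tm != "unassigned"])
  })
  expect_true(all(diff(accs) >= -0.005))   # monotone up to tiny jitter
  expect_gte(accs[3], accs[1])
})
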