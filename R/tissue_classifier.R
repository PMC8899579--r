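#' Supervised cell tissue classification
#'
#' Assigns each cell one of the tissue classes (tumor, connective, necrosis)
#' with a random forest trained on labeled cells, using marker intensities
#' (log1p-transformed) as features. Any classifier meeting the accuracy
#' contract would do; a random forest is robust to the skewed, collinear
#' marker distributions without tuning.
#'
#' @param train a `cell_table` with a `tissue_class` column (>= 2 classes,
#'   >= 20 cells per class)
#' @param cells a `cell_table` to classify
#' @param feature_markers markers to use as features; default: full panel
#'   intersected with the available columns
#' @param ntree number of trees
#' @param seed RNG seed (classification is deterministic given the seed)
#' @return `cells` with a `tissue_class` column
#' @export
classify_cell_tissue <- function(train, cells, feature_markers = NULL,
                                 ntree = 200, seed = 1) {
  stopifnot(inherits(train, "cell_table"), inherits(cells, "cell_table"))
  if (!"tissue_class" %in% names(train))
    stop("training table lacks tissue_class labels")
  y <- factor(train$tissue_class, levels = tissue_classes())
  tab <- table(droplevels(y))
  if (length(tab) < 2) stop("training set contains a single class")
  if (any(tab < 20)) stop("need >= 20 training cells per class; got: ",
                          paste(names(tab), tab, sep = "=", collapse = ", "))
  feature_markers <- feature_markers %||%
    intersect(cell_markers(train), cell_markers(cells))
  feature_markers <- normalize_marker_names(feature_markers)
  miss <- setdiff(feature_markers, intersect(names(train), names(cells)))
  if (length(miss)) stop("feature marker(s) absent: ", paste(miss, collapse = ", "))
  xtr <- log1p(as.matrix(as.data.frame(train)[feature_markers]))
  xte <- log1p(as.matrix(as.data.frame(cells)[feature_markers]))
  set.seed(split_seed(seed, "cell-tissue-rf"))
  fit <- randomForest::randomForest(x = xtr, y = droplevels(y), ntree = ntree)
  cells$tissue_class <- as.character(stats::predict(fit, xte))
  attr(cells, "tissue_classifier") <- fit
  cells
}
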