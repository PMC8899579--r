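#' Tissue class vocabulary
#'
#' The three tissue categories used throughout the pipeline, in the fixed
#' order that also breaks classification ties, plus the auxiliary labels.
#'
#' @export
tissue_classes <- function() c("tumor", "connective", "necrosis")

#' @rdname tissue_classes
#' @export
all_labels <- function() c(tissue_classes(), "background", "unassigned")

#' Per-pixel tissue label map
#'
#' A categorical field over the MSI grid. `labels` is an ny x nx character
#' matrix indexed `[iy + 1, ix + 1]` with values from [all_labels()];
#' `provenance` records how each pixel got its label (`vote`, `knn`,
#' `kmeans_background` or `none`).
#'
#' @param labels character matrix of labels
#' @param provenance optional character matrix, same shape
#' @return a `tissue_label_map`
#' @export
tissue_label_map <- function(labels, provenance = NULL) {
  stopifnot(is.matrix(labels))
  bad <- setdiff(unique(as.vector(labels)), all_labels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (is.null(provenance)) {
    provenance <- matrix("none", nrow(labels), ncol(labels))
  }
  stopifnot(identical(dim(provenance), dim(labels)))
  structure(list(labels = labels, provenance = provenance,
                 nx = ncol(labels), ny = nrow(labels)),
            class = "tissue_label_map")
}

#' @export
print.tissue_label_map <- function(x, ...) {
  cat("<tissue_label_map> ", x$nx, "x", x$ny, " pixels\n", sep = "")
  print(table(factor(x$labels, levels = all_labels())))
  invisible(x)
}

#' Label map agreement
#'
#' Fraction of pixels on which two label maps agree, optionally restricted to
#' a pixel subset.
#'
#' @param a,b `tissue_label_map`s of identical shape
#' @param subset optional logical matrix selecting pixels
#' @return a single number in [0, 1]
#' @export
label_agreement <- function(a, b, subset = NULL) {
  stopifnot(identical(dim(a$labels), dim(b$labels)))
  keep <- if (is.null(subset)) rep(TRUE, length(a$labels)) else as.vector(subset)
  mean(a$labels[keep] == b$labels[keep])
}

#' Write a label map as a long-format CSV (ix, iy, label, provenance)
#' @param x a `tissue_label_map`
#' @param path output file
#' @export
write_label_map <- function(x, path) {
  ix <- rep(seq_len(x$nx) - 1L, each = x$ny)
  iy <- rep(seq_len(x$ny) - 1L, times = x$nx)
  utils::write.csv(data.frame(ix = ix, iy = iy,
                              label = as.vector(x$labels),
                              provenance = as.vector(x$provenance)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
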