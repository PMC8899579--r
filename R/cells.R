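# IMC single-cell tables. Cells enter as segmented-object exports: one row
# per cell with centroid (um, IMC frame), area and per-marker mean intensity.

# canonical marker names of the 27-plex panel
panel_markers <- function() c(
  "aSMA", "Vimentin", "Collagen1", "CD68", "CleavedCaspase3", "PanCK",
  "Ly6G", "Desmin", "CD11c", "CD11b", "F480", "CD163", "ECadherin",
  "pNDRG1", "GLUT1", "pAMPK", "CD31", "EpCAM", "Ki67", "CD206", "Arg1",
  "pS6", "TTF1", "gH2AX", "MHCII", "CD45", "pHH3")

#' Canonicalize marker names
#'
#' Marker spellings vary across export tools ("F4/80", "αSMA",
#' "EpCam (CD326)", ...); names are matched case-insensitively after
#' stripping punctuation, with a small alias table for the usual variants.
#'
#' @param x character vector of marker names
#' @return canonical marker names (unmatched names are returned cleaned)
#' @export
normalize_marker_names <- function(x) {
  clean <- tolower(gsub("[^[:alnum:]]", "", x))
  clean <- sub("α", "a", clean, fixed = TRUE)
  clean <- sub("γ", "g", clean, fixed = TRUE)
  canon <- panel_markers()
  lut <- stats::setNames(canon, tolower(gsub("[^[:alnum:]]", "", canon)))
  aliases <- c(f480 = "F480", sma = "aSMA", asma = "aSMA",
               ecadherin = "ECadherin", epcam = "EpCAM", epcamcd326 = "EpCAM",
               cd326 = "EpCAM", collagen1 = "Collagen1", collageni = "Collagen1",
               cleavedcaspase3 = "CleavedCaspase3", cc3 = "CleavedCaspase3",
               panck = "PanCK", pancytokeratin = "PanCK",
               mhcii = "MHCII", mhciiiaie = "MHCII", iaie = "MHCII",
               yh2ax = "gH2AX", gh2ax = "gH2AX", h2ax = "gH2AX",
               desmin = "Desmin")
  lut <- c(lut, aliases[setdiff(names(aliases), names(lut))])
  out <- unname(lut[clean])
  miss <- is.na(out)
  out[miss] <- x[miss]
  out
}

#' IMC cell table
#'
#' A data frame with one row per segmented cell: `cell_id`, centroid
#' `x_um`/`y_um` (IMC frame), `area_um2`, and one nonnegative intensity
#' column per marker. Marker columns are renamed to canonical panel names.
#'
#' @param df data frame of cell records
#' @param markers character vector naming the marker columns of `df`;
#'   defaults to every column beyond the positional ones
#' @return an object of class `cell_table` (still a data frame)
#' @export
cell_table <- function(df, markers = NULL) {
  df <- as.data.frame(df)
  need <- c("cell_id", "x_um", "y_um", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cell table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("cell_id must be unique")
  if (any(df$area_um2 <= 0)) stop("area_um2 must be positive")
  if (is.null(markers)) {
    markers <- setdiff(names(df), c(need, "phenotype", "tissue_class",
                                    grep("^(positive_|is_)", names(df), value = TRUE),
                                    "ix", "iy", "in_bounds", "x_msi_um", "y_msi_um"))
  }
  canon <- normalize_marker_names(markers)
  names(df)[match(markers, names(df))] <- canon
  for (m in canon) {
    if (!is.numeric(df[[m]])) stop("marker column not numeric: ", m)
    if (any(df[[m]] < 0)) stop("negative intensities in marker: ", m)
  }
  structure(df, markers = canon, class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x), " cells, ", length(attr(x, "markers")),
      " markers", sep = "")
  if ("phenotype" %in% names(x)) cat("; gated")
  if ("tissue_class" %in% names(x)) cat("; tissue-classified")
  cat("\n")
  invisible(x)
}

cell_markers <- function(cells) attr(cells, "markers")

#' Read / write cell tables as CSV
#'
#' Header-driven CSV with one row per cell; marker columns are canonicalized
#' on read.
#'
#' @param path CSV file path
#' @return a `cell_table`
#' @export
read_cells <- function(path) {
  cell_table(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_cells
#' @param cells a `cell_table`
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply marker positivity thresholds
#'
#' Mirrors manual gating: a cell is positive for marker m when its mean
#' intensity is greater than or equal to the threshold (boundary inclusive).
#' Adds one logical `positive_<marker>` column per thresholded marker.
#'
#' @param cells a `cell_table`
#' @param thresholds named numeric vector, marker -> threshold
#' @return the cell table with positivity columns
#' @export
apply_thresholds <- function(cells, thresholds) {
  stopifnot(inherits(cells, "cell_table"), length(thresholds) > 0)
  nm <- normalize_marker_names(names(thresholds))
  miss <- setdiff(nm, names(cells))
  if (length(miss)) stop("no intensity column for marker(s): ",
                         paste(miss, collapse = ", "))
  for (i in seq_along(nm)) {
    cells[[paste0("positive_", nm[i])]] <- cells[[nm[i]]] >= thresholds[i]
  }
  cells
}

positivity <- function(cells, marker) {
  col <- paste0("positive_", marker)
  if (!col %in% names(cells))
    stop("positivity not applied for marker: ", marker,
         " (missing threshold?)")
  cells[[col]]
}

#' Percent positive cells
#'
#' 100 x (positive cells in region) / (cells in region), the summary used to
#' compare marker abundance across whole tissue or the tumor-cell compartment.
#'
#' @param cells a thresholded `cell_table`
#' @param marker marker name
#' @param region optional logical vector selecting the denominator cells
#' @return percentage in [0, 100]; `NA` for an empty region
#' @export
percent_positive <- function(cells, marker, region = NULL) {
  marker <- normalize_marker_names(marker)
  pos <- positivity(cells, marker)
  region <- region %||% rep(TRUE, nrow(cells))
  stopifnot(length(region) == nrow(cells))
  if (!any(region)) return(NA_real_)
  100 * sum(pos[region]) / sum(region)
}
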