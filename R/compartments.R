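# Compartment-resolved drug quantification: the share of total drug ion
# signal in each tissue class per section, and timecourse aggregation.

#' Drug signal fraction per tissue compartment
#'
#' For each class c, fraction_c = (sum of drug intensity over pixels labeled
#' c) / (sum over all pixels of the included classes). Background is never
#' included; necrosis is tissue and is included in the denominator by
#' default (drop it from `classes` to exclude). Fractions are invariant to
#' any positive rescaling of the drug image, so raw or reference-normalized
#' images give the same answer.
#'
#' @param drug an `ion_image`
#' @param labels a `tissue_label_map` on the same grid
#' @param classes classes included in the normalization
#' @param section_id,timepoint_h optional metadata carried into summaries
#' @return a `compartment_fractions` data frame: class, drug_signal,
#'   fraction, pixel_count
#' @export
drug_fraction_by_class <- function(drug, labels, classes = tissue_classes(),
                                   section_id = NA_character_,
                                   timepoint_h = NA_real_) {
  stopifnot(inherits(drug, "ion_image"), inherits(labels, "tissue_label_map"),
            identical(dim(drug$values), dim(labels$labels)))
  v <- drug$values
  ok <- drug$valid & is.finite(v)
  sums <- vapply(classes, function(cl) {
    sel <- ok & labels$labels == cl
    sum(v[sel])
  }, 0)
  counts <- vapply(classes, function(cl) sum(ok & labels$labels == cl), 0L)
  total <- sum(sums)
  if (total <= 0) stop("zero total drug signal over the included classes")
  out <- data.frame(class = classes, drug_signal = unname(sums),
                    fraction = unname(sums) / total,
                    pixel_count = unname(counts))
  attr(out, "total_drug_signal") <- total
  attr(out, "section_id") <- section_id
  attr(out, "timepoint_h") <- timepoint_h
  attr(out, "mean_intensity_section") <- if (any(ok)) mean(v[ok]) else NA_real_
  tum <- ok & labels$labels == "tumor"
  attr(out, "mean_intensity_tumor") <- if (any(tum)) mean(v[tum]) else NA_real_
  class(out) <- c("compartment_fractions", "data.frame")
  out
}

#' Timecourse summary of compartment fractions
#'
#' Aggregates per-section compartment fractions by timepoint: mean and sd of
#' each class fraction and of the mean drug intensity over the whole section
#' and the tumor compartment only. Rows are ordered by timepoint; sd is NA
#' for a single section.
#'
#' @param fractions_list list of `compartment_fractions`
#' @return a data frame (timepoint_h, class, mean_fraction, sd_fraction,
#'   n_sections) with attribute `"intensity"` holding the per-timepoint
#'   intensity summary
#' @export
timecourse_summary <- function(fractions_list) {
  stopifnot(length(fractions_list) >= 1)
  long <- do.call(rbind, lapply(fractions_list, function(f) {
    data.frame(timepoint_h = attr(f, "timepoint_h"),
               section_id = attr(f, "section_id"),
               class = f$class, fraction = f$fraction,
               mean_intensity_section = attr(f, "mean_intensity_section"),
               mean_intensity_tumor = attr(f, "mean_intensity_tumor"))
  }))
  agg <- stats::aggregate(fraction ~ timepoint_h + class, long, function(x)
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x)))
  out <- data.frame(timepoint_h = agg$timepoint_h, class = agg$class,
                    mean_fraction = agg$fraction[, "mean"],
                    sd_fraction = agg$fraction[, "sd"],
                    n_sections = as.integer(agg$fraction[, "n"]))
  out <- out[order(out$timepoint_h, match(out$class, tissue_classes())), ]
  rownames(out) <- NULL
  per_sec <- unique(long[c("timepoint_h", "section_id",
                           "mean_intensity_section", "mean_intensity_tumor")])
  istat <- function(col) {
    a <- stats::aggregate(per_sec[[col]], list(timepoint_h = per_sec$timepoint_h),
                          function(x) c(mean(x), if (length(x) > 1) stats::sd(x) else NA_real_))
    a
  }
  a1 <- istat("mean_intensity_section"); a2 <- istat("mean_intensity_tumor")
  intensity <- data.frame(timepoint_h = a1$timepoint_h,
                          mean_section_intensity = a1$x[, 1],
                          sd_section_intensity = a1$x[, 2],
                          mean_tumor_intensity = a2$x[, 1],
                          sd_tumor_intensity = a2$x[, 2])
  intensity <- intensity[order(intensity$timepoint_h), ]
  rownames(intensity) <- NULL
  attr(out, "intensity") <- intensity
  out
}

#' Write a timecourse table as CSV
#' @param tc result of [timecourse_summary()]
#' @param path output file
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(tc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
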