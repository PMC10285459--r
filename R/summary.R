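#' Density subset labels
#'
#' Images are binned by instance count into the survey density subsets:
#' 1-9 instances is "sparse", 10-19 "medium", 20 and above "dense".
#' Images without instances are left unlabeled (`NA`).
#'
#' @param records List of `annotation_record`s.
#' @return Named character vector, one label per record, named by image id.
#' @export
split_subsets <- function(records) {
  counts <- vapply(records, n_instances, integer(1))
  lab <- rep(NA_character_, length(counts))
  lab[counts >= 1 & counts <= 9] <- "sparse"
  lab[counts >= 10 & counts <= 19] <- "medium"
  lab[counts >= 20] <- "dense"
  names(lab) <- vapply(records, function(r) r$image_id, character(1))
  lab
}

# aspect-ratio bin edges over w/h; last bin is open-ended
ASPECT_BREAKS <- c(1, 2, 3, 5, 8, Inf)

#' Summarize an annotated dataset
#'
#' Counts images and instances, reports the mean number of instances per
#' image (rounded to 2 decimals, the conventional reporting precision),
#' histograms of the instance aspect ratio `w/h` (bins `[1,2), [2,3),
#' [3,5), [5,8), [8,Inf)`) and of the long-edge angle (8 equal bins over
#' `[-pi/4, 3*pi/4)`), and the density subset label of every image.
#' Histogram totals always equal the instance total.
#'
#' @param records Non-empty list of rotated `annotation_record`s.
#' @return A `dataset_summary` list with fields `n_images`, `n_instances`,
#'   `mean_instances_per_image`, `aspect_ratio_histogram`,
#'   `angle_histogram`, `subset_labels`.
#' @export
dataset_summary <- function(records) {
  if (length(records) == 0L)
    stop("dataset_summary requires at least one record", call. = FALSE)
  counts <- vapply(records, n_instances, integer(1))
  boxes <- do.call(rbind, lapply(records, function(r) unclass(r$instances)))
  n_inst <- sum(counts)
  if (n_inst > 0L) {
    aspect <- boxes[, "w"] / boxes[, "h"]
    asp_bin <- cut(aspect, breaks = ASPECT_BREAKS, right = FALSE,
                   include.lowest = TRUE)
    asp_hist <- as.integer(table(asp_bin))
    names(asp_hist) <- levels(asp_bin)
    ang_breaks <- seq(-pi / 4, 3 * pi / 4, length.out = 9)
    ang_bin <- cut(boxes[, "theta"], breaks = ang_breaks, right = FALSE,
                   include.lowest = TRUE)
    ang_hist <- as.integer(table(ang_bin))
    names(ang_hist) <- levels(ang_bin)
  } else {
    asp_hist <- integer(5)
    ang_hist <- integer(8)
  }
  structure(list(
    n_images = length(records),
    n_instances = n_inst,
    mean_instances_per_image = round(n_inst / length(records), 2),
    aspect_ratio_histogram = asp_hist,
    angle_histogram = ang_hist,
    subset_labels = split_subsets(records)
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d image(s), %d instance(s), mean %.2f/image\n",
              x$n_images, x$n_instances, x$mean_instances_per_image))
  tab <- table(factor(x$subset_labels, levels = c("sparse", "medium", "dense")),
               useNA = "ifany")
  cat("  subsets:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Write a dataset summary as JSON
#'
#' @param summary A `dataset_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
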