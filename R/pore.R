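#' Parameters of the connected-component pore-size feature
#'
#' @param threshold binarisation threshold on the 8-bit intensity scale; a
#'   pixel is lumen (foreground) iff its intensity is strictly greater than
#'   the threshold.  The default 180 was determined empirically for
#'   transmitted-light sections in which lumens are the bright phase.
#' @param connectivity pixel connectivity for labelling, 4 (default) or 8.
#' @param bin_width histogram bin width in log10 units of equivalent size.
#' @param bin_range half-open `[low, high)` range of log10(size) covered by
#'   the fixed histogram grid; sizes are `sqrt(area)` in micrometres (or
#'   pixels, see `units`).
#' @param units `"um"` to measure component sizes in micrometres via the
#'   image scale, `"px"` for raw pixel units.
#' @return an object of class `pore_params`.
#' @export
pore_params <- function(threshold = 180, connectivity = 4, bin_width = 0.1,
                        bin_range = c(0, 3), units = c("um", "px")) {
  units <- match.arg(units)
  if (threshold <= 0 || threshold >= 255)
    stop("`threshold` must lie strictly between 0 and 255", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (length(bin_range) != 2L || bin_range[1] >= bin_range[2])
    stop("`bin_range` must be c(low, high) with low < high", call. = FALSE)
  structure(list(threshold = threshold, connectivity = as.integer(connectivity),
                 bin_width = bin_width, bin_range = as.numeric(bin_range),
                 units = units),
            class = "pore_params")
}

#' Binarise a micrograph into a lumen mask
#'
#' @param image a [micrograph()] or numeric matrix of 8-bit intensities.
#' @param params a [pore_params()].
#' @return logical matrix; `TRUE` where intensity strictly exceeds the
#'   threshold (lumens are the bright phase).
#' @export
binarize <- function(image, params = pore_params()) {
  px <- as_pixels(image)
  px > params$threshold
}

#' Label connected components of a binary mask
#'
#' Maximal 4-connected (or 8-connected) foreground regions, labelled
#' 1..n in column-major scan order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @param scale micrometres per pixel used for the area/size conversion.
#' @return a `component_table`: data frame with `id`, `area_px`, `area_um2`
#'   and `size` (`sqrt(area)`, micrometre units unless `scale = 1` pixel
#'   mode is intended); the label matrix is attached as attribute `labels`.
#' @export
label_components <- function(mask, connectivity = 4, scale = 1) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!is.logical(mask)) mask <- mask > 0
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  lab <- .cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  area_px <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  tab <- data.frame(id = seq_len(n), area_px = area_px,
                    area_um2 = area_px * scale^2,
                    size = sqrt(area_px * scale^2))
  class(tab) <- c("component_table", "data.frame")
  attr(tab, "labels") <- lab
  attr(tab, "scale") <- scale
  tab
}

#' Binarise and label a micrograph in one step
#'
#' @inheritParams binarize
#' @return a `component_table` (see [label_components()]); sizes are in
#'   micrometres when `params$units == "um"`, else pixels.
#' @export
pore_components <- function(image, params = pore_params()) {
  scale <- if (params$units == "um" && is_micrograph(image)) image$scale else 1
  label_components(binarize(image, params), params$connectivity, scale = scale)
}

#' Log-log pore-size histogram feature
#'
#' Bins each component's `log10(sqrt(area))` into the fixed half-open grid
#' `[low, low + bin_width), ...` and stores `log10(count + 1)` per bin, so
#' that empty bins map to 0 and counts are recoverable as
#' `10^log_counts - 1`.  Components falling outside `bin_range` are counted
#' in `n_out_of_range` but excluded from the vector.
#'
#' @param table a `component_table` (possibly empty).
#' @param params a [pore_params()].
#' @return an object of class `pore_histogram` with fields `bin_edges`
#'   (lower edges, length `nbins`), `log_counts`, `n_components` (in-range)
#'   and `n_out_of_range`.
#' @export
histogram_features <- function(table, params = pore_params()) {
  lo <- params$bin_range[1]; hi <- params$bin_range[2]
  nbins <- round((hi - lo) / params$bin_width)
  sizes <- table$size
  sizes <- sizes[sizes > 0]
  logs <- log10(sizes)
  bin <- floor((logs - lo) / params$bin_width) + 1L
  in_range <- bin >= 1L & bin <= nbins & logs < hi & logs >= lo
  counts <- tabulate(bin[in_range], nbins = nbins)
  structure(list(bin_edges = lo + (seq_len(nbins) - 1L) * params$bin_width,
                 log_counts = log10(counts + 1),
                 n_components = sum(in_range),
                 n_out_of_range = sum(!in_range)),
            class = "pore_histogram")
}

#' @exportS3Method base::print
print.pore_histogram <- function(x, ...) {
  cat(sprintf("<pore_histogram> %d bins, %d components in range (%d outside)\n",
              length(x$log_counts), x$n_components, x$n_out_of_range))
  invisible(x)
}

#' Per-class mean pore histograms
#'
#' Element-wise mean of `log_counts` within each class, the per-species
#' summary used to compare size distributions across taxa.
#'
#' @param histograms list of `pore_histogram` objects on a common grid.
#' @param labels class label per histogram.
#' @return matrix with one row per class (rownames = class labels) and one
#'   column per bin.
#' @export
average_by_class <- function(histograms, labels) {
  if (length(histograms) == 0L || length(histograms) != length(labels))
    stop("`histograms` and `labels` must have equal positive length", call. = FALSE)
  m <- t(vapply(histograms, `[[`, numeric(length(histograms[[1]]$log_counts)),
                "log_counts"))
  if (any(table(labels) < 1L)) stop("empty class", call. = FALSE)
  grp <- rowsum(m, group = labels)
  grp / as.vector(table(labels)[rownames(grp)])
}

#' Pore-histogram feature table for a set of micrographs
#'
#' @param images list of [micrograph()] objects with labels.
#' @param params a [pore_params()].
#' @return a [feature_table()] whose rows are `log_counts` vectors.
#' @export
pore_feature_table <- function(images, params = pore_params()) {
  rows <- lapply(images, function(im)
    histogram_features(pore_components(im, params), params)$log_counts)
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("logsize_%.1f", params$bin_range[1] +
                           (seq_len(ncol(x)) - 1L) * params$bin_width)
  feature_table(x,
                labels = vapply(images, function(im) im$label %||% NA_character_, ""),
                group_ids = vapply(images, function(im) im$individual_id %||% NA_character_, ""),
                image_ids = seq_along(images))
}
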