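#' Micrograph container
#'
#' An 8-bit grayscale transverse-section image together with its physical
#' scale and optional metadata: a class (species/taxon) label, a specimen
#' identifier, and -- for synthetic images -- a ground-truth pore mask with
#' the rendered pore areas.
#'
#' @param pixels numeric or integer matrix of intensities in `[0, 255]`
#'   (rows = image y, columns = image x).
#' @param scale physical scale in micrometres per pixel.
#' @param label optional class label (species / taxon), a single string.
#' @param individual_id optional specimen identifier.
#' @param truth_mask optional integer matrix of the same dimension as
#'   `pixels`; `0` is background and positive values are pore ids.
#' @param truth_areas optional numeric vector of pore areas in square
#'   micrometres, one per distinct nonzero id of `truth_mask`.
#'
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(pixels, scale, label = NULL, individual_id = NULL,
                       truth_mask = NULL, truth_areas = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must be finite and within [0, 255]", call. = FALSE)
  stop_if_not_scalar_pos(scale, "scale")
  if (!is.null(truth_mask)) {
    if (!identical(dim(truth_mask), dim(pixels)))
      stop("`truth_mask` must match the pixel dimensions", call. = FALSE)
    ids <- sort(unique(truth_mask[truth_mask > 0]))
    if (length(ids) != length(truth_areas))
      stop("`truth_areas` must have one entry per distinct nonzero mask id",
           call. = FALSE)
  } else if (!is.null(truth_areas) && length(truth_areas) > 0) {
    stop("`truth_areas` given without `truth_mask`", call. = FALSE)
  }
  structure(
    list(pixels = pixels, scale = scale, label = label,
         individual_id = individual_id, truth_mask = truth_mask,
         truth_areas = truth_areas),
    class = "micrograph"
  )
}

#' @exportS3Method base::print
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.3g um/px (%.2f x %.2f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              nrow(x$pixels) * x$scale / 1000, ncol(x$pixels) * x$scale / 1000))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$individual_id)) cat("  individual:", x$individual_id, "\n")
  if (!is.null(x$truth_mask))
    cat(sprintf("  ground truth: %d pores\n", length(x$truth_areas)))
  invisible(x)
}

#' Test for the micrograph class
#' @param x object.
#' @return logical.
#' @export
is_micrograph <- function(x) inherits(x, "micrograph")

# Coerce a micrograph or a bare matrix to an intensity matrix.
as_pixels <- function(image) {
  if (is_micrograph(image)) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected a micrograph or a numeric matrix", call. = FALSE)
}
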