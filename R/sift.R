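#' SIFT detector parameters
#'
#' Defaults follow Lowe's reference formulation as exposed by mainstream
#' implementations: 3 layers per octave, base Gaussian scale 1.6, contrast
#' threshold 0.06 and principal-curvature (edge) threshold 10.
#'
#' @param n_octave_layers scales per octave used for extrema detection.
#' @param sigma base Gaussian scale of the pyramid.
#' @param contrast_threshold minimum absolute interpolated
#'   difference-of-Gaussian response (on a `[0, 1]` intensity scale,
#'   multiplied internally by the layer count).
#' @param edge_threshold maximum ratio of principal curvatures.
#' @param double_size if `TRUE` (default, as in the reference algorithm) the
#'   image is doubled before building the pyramid, adding a -1 octave.
#' @return an object of class `sift_params`.
#' @export
sift_params <- function(n_octave_layers = 3L, sigma = 1.6,
                        contrast_threshold = 0.06, edge_threshold = 10,
                        double_size = TRUE) {
  stopifnot(n_octave_layers >= 1, sigma > 0, contrast_threshold > 0,
            edge_threshold > 0)
  structure(list(n_octave_layers = as.integer(n_octave_layers), sigma = sigma,
                 contrast_threshold = contrast_threshold,
                 edge_threshold = edge_threshold,
                 double_size = isTRUE(double_size)),
            class = "sift_params")
}

#' Detect SIFT keypoints and descriptors
#'
#' Difference-of-Gaussian extrema over a Gaussian scale-space pyramid with
#' sub-pixel/sub-scale refinement, contrast and edge rejection, gradient
#' orientation assignment (one keypoint per dominant orientation) and the
#' 4x4x8 gradient-orientation descriptor, kept as unit-norm floats after the
#' usual 0.2 clamp and renormalisation.
#'
#' @param image a [micrograph()] or an 8-bit grayscale matrix.
#' @param params a [sift_params()].
#' @return an object of class `sift_keypoints`: a list with `keypoints`
#'   (data frame: `x`, `y` in 1-based image coordinates, `scale` as the
#'   detection sigma in input pixels, `orientation` in radians,
#'   `response`, `octave`) and `descriptors` (n x 128 matrix).
#' @export
detect_keypoints <- function(image, params = sift_params()) {
  px <- as_pixels(image)
  if (is.array(px) && length(dim(px)) == 3L)
    stop("`image` must be single-channel grayscale", call. = FALSE)
  res <- .cpp_sift(px, params$n_octave_layers, params$sigma,
                   params$contrast_threshold, params$edge_threshold,
                   params$double_size)
  kp <- as.data.frame(res$keypoints)
  # C++ coordinates are 0-based; shift to R's 1-based pixel indexing
  if (nrow(kp) > 0) { kp$x <- kp$x + 1; kp$y <- kp$y + 1 }
  structure(list(keypoints = kp, descriptors = res$descriptors),
            class = "sift_keypoints")
}

#' @exportS3Method base::print
print.sift_keypoints <- function(x, ...) {
  cat(sprintf("<sift_keypoints> %d keypoints\n", nrow(x$keypoints)))
  invisible(x)
}

#' Aggregate descriptors into a bag feature
#'
#' The per-image shape feature: descriptors summed over all keypoints and
#' divided by the keypoint count, i.e. the element-wise mean descriptor.
#'
#' @param keypoints a `sift_keypoints` object or an n x 128 descriptor
#'   matrix with at least one row.
#' @return an object of class `bag_feature`: list with `values` (length-128
#'   numeric) and `n_keypoints`.
#' @export
aggregate_descriptors <- function(keypoints) {
  d <- if (inherits(keypoints, "sift_keypoints")) keypoints$descriptors
       else as.matrix(keypoints)
  if (is.null(dim(d)) || nrow(d) == 0L)
    stop("no keypoints: cannot aggregate an empty descriptor set", call. = FALSE)
  if (ncol(d) != 128L) stop("descriptors must have 128 columns", call. = FALSE)
  structure(list(values = colMeans(d), n_keypoints = nrow(d)),
            class = "bag_feature")
}

#' SIFT bag-of-descriptors feature table for a set of micrographs
#'
#' Images yielding zero keypoints are excluded with a warning (a zero vector
#' is not a mean and would distort the discriminant fit).
#'
#' @param images list of labelled [micrograph()] objects.
#' @param params a [sift_params()].
#' @param keep_keypoints if `TRUE`, the per-image `sift_keypoints` objects
#'   are attached as attribute `"keypoints"` (used by the keypoint atlas).
#' @return a [feature_table()] with 128 columns; the per-image keypoint
#'   count is attached as attribute `"n_keypoints"`.
#' @export
sift_feature_table <- function(images, params = sift_params(),
                               keep_keypoints = FALSE) {
  kps <- lapply(images, detect_keypoints, params = params)
  n_kp <- vapply(kps, function(k) nrow(k$keypoints), 0L)
  keep <- n_kp > 0L
  if (!all(keep))
    warning(sprintf("%d image(s) yielded no keypoints and were dropped",
                    sum(!keep)), call. = FALSE)
  rows <- lapply(kps[keep], function(k) aggregate_descriptors(k)$values)
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("d%03d", seq_len(128L))
  ft <- feature_table(
    x,
    labels = vapply(images[keep], function(im) im$label %||% NA_character_, ""),
    group_ids = vapply(images[keep], function(im) im$individual_id %||% NA_character_, ""),
    image_ids = which(keep))
  attr(ft, "n_keypoints") <- n_kp[keep]
  if (keep_keypoints) attr(ft, "keypoints") <- kps[keep]
  ft
}
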