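#' Resize ladder
#'
#' A strictly decreasing sequence of side lengths through which an image is
#' downscaled step by step; the last entry is the target size.
#'
#' @param sizes numeric vector, strictly decreasing, all >= 16.
#' @return an object of class `resize_ladder`.
#' @export
resize_ladder <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(diff(sizes) >= 0) || any(sizes < 16))
    stop("ladder sizes must be strictly decreasing and all >= 16", call. = FALSE)
  structure(sizes, class = "resize_ladder")
}

#' Default stepwise-downscaling ladder
#'
#' The default schedule `{3600, 1800, 900, 720, 600, 450, 360, 225, 112}`,
#' truncated to the sizes strictly between the source side and the target
#' and terminated at the target.  It contains every side length used by the
#' classification-vs-resolution sweep while avoiding aliasing from a single
#' large hop.
#'
#' @param target target side length in pixels.
#' @param source_side side length of the source image.
#' @return a [resize_ladder()].
#' @export
default_ladder <- function(target, source_side) {
  base <- c(3600L, 1800L, 900L, 720L, 600L, 450L, 360L, 225L, 112L)
  if (target > source_side)
    stop("target size exceeds the source image", call. = FALSE)
  steps <- base[base < source_side & base > target]
  resize_ladder(c(steps, target))
}

#' Centre-crop an image to a square
#'
#' @param image a [micrograph()] or numeric matrix.
#' @return same type as the input, cropped to side `min(nrow, ncol)`;
#'   the physical scale is unchanged.
#' @export
crop_square <- function(image) {
  px <- as_pixels(image)
  if (length(px) == 0L) stop("empty image", call. = FALSE)
  h <- nrow(px); w <- ncol(px)
  side <- min(h, w)
  r0 <- (h - side) %/% 2L
  c0 <- (w - side) %/% 2L
  out <- px[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
  if (is_micrograph(image)) {
    image$pixels <- out
    if (!is.null(image$truth_mask)) {
      image$truth_mask <- image$truth_mask[(r0 + 1L):(r0 + side),
                                           (c0 + 1L):(c0 + side), drop = FALSE]
      kept <- sort(unique(image$truth_mask[image$truth_mask > 0]))
      image$truth_areas <- image$truth_areas[kept]
      image$truth_mask[] <- match(image$truth_mask, kept, nomatch = 0L)
      # recompute areas from the cropped mask so mask and areas stay in sync
      if (length(kept))
        image$truth_areas <- as.numeric(tabulate(image$truth_mask[image$truth_mask > 0],
                                                 nbins = length(kept))) * image$scale^2
    }
    image
  } else out
}

#' Convert an image to 8-bit grayscale
#'
#' Single-channel input with a range beyond 8 bits is rescaled linearly from
#' the 16-bit range to `[0, 255]`; 3-channel input is converted with the
#' ITU-R BT.601 luminance weights (0.299, 0.587, 0.114).  8-bit grayscale
#' input is returned unchanged.
#'
#' @param image a numeric matrix (1 channel), a 3-dimensional array with 3
#'   channels, or a [micrograph()].
#' @return numeric matrix in `[0, 255]` (or a micrograph if one was given).
#' @export
to_gray8 <- function(image) {
  if (is_micrograph(image)) {
    image$pixels <- to_gray8(image$pixels)
    return(image)
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) {
      image <- image[, , 1L]
    } else if (dim(image)[3] == 3L) {
      image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
        0.114 * image[, , 3L]
    } else {
      stop("only 1- or 3-channel images are supported", call. = FALSE)
    }
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop("only 1- or 3-channel images are supported", call. = FALSE)
  if (max(image) <= 1 && min(image) >= 0 && !all(image == round(image))) {
    image <- image * 255          # [0,1] float convention (e.g. PNG readers)
  } else if (max(image) > 255) {
    image <- image * 255 / 65535  # 16-bit range
  }
  matrix(pmin(255, pmax(0, round(image))), nrow(image), ncol(image))
}

#' Stepwise bilinear downscaling
#'
#' Resizes through each ladder entry in turn using bilinear interpolation,
#' requantising to 8 bits after every hop (mimicking a pipeline that stores
#' 8-bit intermediates).  The physical scale is multiplied by
#' `source_side / target_side` at each step, so the final micrograph knows
#' its effective um/pixel.  Ground-truth masks do not survive resampling and
#' are dropped.
#'
#' @param image a square [micrograph()] or matrix.
#' @param ladder a [resize_ladder()] whose first entry does not exceed the
#'   image side; defaults to [default_ladder()] for the requested `target`.
#' @param target target side, used only when `ladder` is missing.
#' @return resized image, same type as input.
#' @export
downscale_stepwise <- function(image, ladder = NULL, target = NULL) {
  px <- as_pixels(image)
  side <- min(dim(px))
  if (nrow(px) != ncol(px))
    stop("image must be square; use crop_square() first", call. = FALSE)
  if (is.null(ladder)) {
    if (is.null(target)) stop("either `ladder` or `target` is required", call. = FALSE)
    ladder <- default_ladder(target, side)
  }
  if (!inherits(ladder, "resize_ladder")) ladder <- resize_ladder(ladder)
  if (ladder[1] > side)
    stop("ladder exceeds the source image size", call. = FALSE)
  scale_mult <- 1
  for (s in as.integer(ladder)) {
    if (s == nrow(px)) next
    scale_mult <- scale_mult * nrow(px) / s
    px <- .cpp_resize_bilinear(px, s, s)
    px <- matrix(pmin(255, pmax(0, round(px))), s, s)
  }
  if (is_micrograph(image)) {
    micrograph(px, scale = image$scale * scale_mult, label = image$label,
               individual_id = image$individual_id)
  } else px
}
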