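#' Porosity profile: the recipe for one synthetic wood class
#'
#' Describes a wood "species" for the synthetic micrograph generator: how
#' vessel lumens (pores) are sized, arranged and rendered on a transverse
#' section.  Three arrangements are supported: `"ring"` (large earlywood
#' vessels confined to a band recurring every growth ring), `"diffuse"`
#' (vessels scattered uniformly) and `"radial"` (vessels aligned in radial
#' files that share a column coordinate).
#'
#' @param class_label class (species) name, a single string.
#' @param arrangement one of `"ring"`, `"diffuse"`, `"radial"`.
#' @param pore_mixture matrix or data frame with columns `mean`, `sd`,
#'   `weight`: a Gaussian mixture of pore diameters in micrometres.  Weights
#'   must sum to 1.
#' @param ring_period growth-ring period in micrometres (ring arrangement
#'   only).
#' @param earlywood_fraction fraction of the ring period occupied by the
#'   earlywood (large-vessel) band, in (0, 1).
#' @param pores_per_mm2 target pore density per square millimetre (the
#'   realised density can be lower when non-overlapping placement fails).
#' @param wall_gray background (cell wall) intensity, 0-255.
#' @param lumen_gray pore lumen intensity, 0-255; must exceed `wall_gray`
#'   (lumens are the bright phase in transmitted light).
#' @param ray_lines_per_mm density of uniseriate rays (thin radial lines).
#' @param ray_width ray width in micrometres.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed default generation seed for this profile.
#' @param earlywood_min_diameter mixture components whose mean diameter is at
#'   least this value (micrometres) are treated as earlywood vessels and, in
#'   ring mode, confined to the earlywood band.
#'
#' @return an object of class `porosity_profile`.
#' @export
porosity_profile <- function(class_label,
                             arrangement = c("diffuse", "ring", "radial"),
                             pore_mixture,
                             ring_period = NULL,
                             earlywood_fraction = NULL,
                             pores_per_mm2,
                             wall_gray = 120,
                             lumen_gray = 230,
                             ray_lines_per_mm = 0.8,
                             ray_width = 12,
                             noise_sd = 10,
                             seed = 1L,
                             earlywood_min_diameter = 100) {
  arrangement <- match.arg(arrangement)
  if (!is.character(class_label) || length(class_label) != 1L || !nzchar(class_label))
    stop("`class_label` must be a non-empty string", call. = FALSE)
  mix <- as.matrix(as.data.frame(pore_mixture)[, c("mean", "sd", "weight")])
  storage.mode(mix) <- "double"
  if (nrow(mix) < 1 || any(!is.finite(mix)))
    stop("`pore_mixture` must have finite mean/sd/weight rows", call. = FALSE)
  if (any(mix[, "mean"] <= 0) || any(mix[, "sd"] < 0) || any(mix[, "weight"] < 0))
    stop("mixture diameters must be positive and sd/weights non-negative",
         call. = FALSE)
  if (abs(sum(mix[, "weight"]) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (!is.numeric(pores_per_mm2) || pores_per_mm2 < 0)
    stop("`pores_per_mm2` must be non-negative", call. = FALSE)
  if (!is.numeric(ray_lines_per_mm) || ray_lines_per_mm < 0)
    stop("`ray_lines_per_mm` must be non-negative", call. = FALSE)
  if (wall_gray < 0 || wall_gray > 255 || lumen_gray < 0 || lumen_gray > 255)
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  if (lumen_gray <= wall_gray)
    stop("`lumen_gray` must exceed `wall_gray` (lumens are the bright phase)",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (arrangement == "ring") {
    stop_if_not_scalar_pos(ring_period, "ring_period")
    if (!is.numeric(earlywood_fraction) || earlywood_fraction <= 0 ||
        earlywood_fraction >= 1)
      stop("`earlywood_fraction` must lie in (0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_pos(ray_width, "ray_width")
  structure(
    list(class_label = class_label, arrangement = arrangement,
         pore_mixture = mix, ring_period = ring_period,
         earlywood_fraction = earlywood_fraction,
         pores_per_mm2 = pores_per_mm2, wall_gray = wall_gray,
         lumen_gray = lumen_gray, ray_lines_per_mm = ray_lines_per_mm,
         ray_width = ray_width, noise_sd = noise_sd, seed = as.integer(seed),
         earlywood_min_diameter = earlywood_min_diameter),
    class = "porosity_profile"
  )
}

#' @exportS3Method base::print
print.porosity_profile <- function(x, ...) {
  cat(sprintf("<porosity_profile> %s (%s-porous), %.3g pores/mm2, %d mixture component(s)\n",
              x$class_label, x$arrangement, x$pores_per_mm2, nrow(x$pore_mixture)))
  invisible(x)
}

mixture_df <- function(mean, sd, weight) data.frame(mean = mean, sd = sd, weight = weight)

#' Default porosity profiles: an 18-class synthetic Fagaceae-like flora
#'
#' Eighteen well-separated wood classes -- six ring-porous, six
#' diffuse-porous and six radial-porous -- whose pore-diameter mixtures span
#' roughly 5-400 um.  Classes differ jointly in mixture modes, pore density,
#' wall/lumen contrast and ray density, mimicking the variation found across
#' a hardwood family.  The set contains a designed confound: the ring-porous
#' `cerris_like` class shares its latewood (small-pore) mixture, contrast
#' and ray layout with the radial-porous `ilex_like` class and differs only
#' by an added earlywood band of large vessels, emulating the classical
#' Cerris/Ilex similarity in oaks.
#'
#' @return a named list of 18 [porosity_profile()] objects.
#' @export
default_profiles <- function() {
  p <- list(
    # -- ring-porous ------------------------------------------------------
    porosity_profile("ring_a", "ring",
      mixture_df(c(280, 26), c(30, 4), c(0.10, 0.90)),
      ring_period = 700, earlywood_fraction = 0.25, pores_per_mm2 = 60,
      wall_gray = 118, lumen_gray = 232, ray_lines_per_mm = 0.8, ray_width = 12),
    porosity_profile("ring_b", "ring",
      mixture_df(c(340, 35), c(40, 6), c(0.08, 0.92)),
      ring_period = 900, earlywood_fraction = 0.30, pores_per_mm2 = 45,
      wall_gray = 128, lumen_gray = 238, ray_lines_per_mm = 0.5, ray_width = 15),
    porosity_profile("ring_c", "ring",
      mixture_df(c(200, 12), c(25, 2), c(0.12, 0.88)),
      ring_period = 500, earlywood_fraction = 0.30, pores_per_mm2 = 90,
      wall_gray = 112, lumen_gray = 226, ray_lines_per_mm = 1.2, ray_width = 10),
    porosity_profile("ring_d", "ring",
      mixture_df(c(250, 45), c(30, 8), c(0.10, 0.90)),
      ring_period = 800, earlywood_fraction = 0.22, pores_per_mm2 = 50,
      wall_gray = 132, lumen_gray = 242, ray_lines_per_mm = 0.6, ray_width = 18),
    porosity_profile("ring_e", "ring",
      mixture_df(c(310, 28), c(35, 5), c(0.07, 0.93)),
      ring_period = 600, earlywood_fraction = 0.35, pores_per_mm2 = 70,
      wall_gray = 122, lumen_gray = 230, ray_lines_per_mm = 1.0, ray_width = 12),
    # designed confound: latewood identical to ilex_like below
    porosity_profile("cerris_like", "ring",
      mixture_df(c(320, 18), c(35, 3), c(0.05, 0.95)),
      ring_period = 750, earlywood_fraction = 0.28, pores_per_mm2 = 100,
      wall_gray = 120, lumen_gray = 231, ray_lines_per_mm = 0.9, ray_width = 12),
    # -- diffuse-porous ---------------------------------------------------
    porosity_profile("diffuse_a", "diffuse",
      mixture_df(60, 10, 1), pores_per_mm2 = 40,
      wall_gray = 115, lumen_gray = 228, ray_lines_per_mm = 0.7, ray_width = 12),
    porosity_profile("diffuse_b", "diffuse",
      mixture_df(85, 14, 1), pores_per_mm2 = 25,
      wall_gray = 125, lumen_gray = 236, ray_lines_per_mm = 0.4, ray_width = 16),
    porosity_profile("diffuse_c", "diffuse",
      mixture_df(40, 7, 1), pores_per_mm2 = 80,
      wall_gray = 110, lumen_gray = 224, ray_lines_per_mm = 1.1, ray_width = 10),
    porosity_profile("diffuse_d", "diffuse",
      mixture_df(110, 18, 1), pores_per_mm2 = 16,
      wall_gray = 130, lumen_gray = 240, ray_lines_per_mm = 0.5, ray_width = 14),
    porosity_profile("diffuse_e", "diffuse",
      mixture_df(c(70, 30), c(12, 6), c(0.6, 0.4)), pores_per_mm2 = 55,
      wall_gray = 120, lumen_gray = 233, ray_lines_per_mm = 0.8, ray_width = 12),
    porosity_profile("diffuse_f", "diffuse",
      mixture_df(c(95, 50), c(15, 8), c(0.5, 0.5)), pores_per_mm2 = 30,
      wall_gray = 135, lumen_gray = 244, ray_lines_per_mm = 0.3, ray_width = 20),
    # -- radial-porous ----------------------------------------------------
    porosity_profile("radial_a", "radial",
      mixture_df(30, 5, 1), pores_per_mm2 = 100,
      wall_gray = 114, lumen_gray = 227, ray_lines_per_mm = 1.3, ray_width = 10),
    porosity_profile("radial_b", "radial",
      mixture_df(48, 8, 1), pores_per_mm2 = 70,
      wall_gray = 124, lumen_gray = 235, ray_lines_per_mm = 0.9, ray_width = 13),
    porosity_profile("radial_c", "radial",
      mixture_df(c(24, 55), c(4, 9), c(0.7, 0.3)), pores_per_mm2 = 110,
      wall_gray = 118, lumen_gray = 229, ray_lines_per_mm = 1.5, ray_width = 9),
    porosity_profile("radial_d", "radial",
      mixture_df(65, 10, 1), pores_per_mm2 = 45,
      wall_gray = 129, lumen_gray = 239, ray_lines_per_mm = 0.6, ray_width = 15),
    porosity_profile("radial_e", "radial",
      mixture_df(c(38, 14), c(6, 3), c(0.5, 0.5)), pores_per_mm2 = 130,
      wall_gray = 116, lumen_gray = 225, ray_lines_per_mm = 1.2, ray_width = 11),
    # partner of the designed confound
    porosity_profile("ilex_like", "radial",
      mixture_df(18, 3, 1), pores_per_mm2 = 120,
      wall_gray = 120, lumen_gray = 231, ray_lines_per_mm = 0.9, ray_width = 12)
  )
  names(p) <- vapply(p, `[[`, "", "class_label")
  p
}

# Rasterise a filled ellipse of area-equivalent radius r_px centred at
# (cx, cy) (1-based continuous coordinates); returns in-bounds linear pixel
# indices of an n x n image.
ellipse_pixels <- function(cx, cy, r_px, axis_ratio, theta, n_row, n_col) {
  a <- r_px * sqrt(axis_ratio)   # semi-major
  b <- r_px / sqrt(axis_ratio)   # semi-minor; a*b = r^2 keeps area
  ext <- ceiling(a)
  xs <- max(1L, floor(cx - ext)):min(n_col, ceiling(cx + ext))
  ys <- max(1L, floor(cy - ext)):min(n_row, ceiling(cy + ext))
  if (length(xs) == 0L || length(ys) == 0L) return(integer(0))
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  row_idx <- rep(ys, times = length(xs))[inside]
  col_idx <- rep(xs, each = length(ys))[inside]
  (col_idx - 1L) * n_row + row_idx
}

#' Generate one synthetic transverse-section micrograph
#'
#' Renders bright elliptical vessel lumens on a darker cell-wall background
#' according to a [porosity_profile()], with uniseriate rays drawn as thin
#' bright lines with dark flanks, then adds Gaussian pixel noise and clips
#' to `[0, 255]`.  Pore placement is non-overlapping by rejection sampling
#' (at most 1000 attempts per pore, larger pores placed first); pores that
#' cannot be placed are skipped, and the ground truth records only rendered
#' pores.  The same `(profile, side_px, scale, seed)` always reproduces
#' byte-identical pixels.
#'
#' @param profile a [porosity_profile()].
#' @param side_px image side length in pixels (>= 64).
#' @param scale micrometres per pixel (default 0.74, typical of a 2x
#'   objective on a 2/3" CCD).
#' @param seed integer seed; defaults to the profile's own seed.
#' @return a [micrograph()] with `truth_mask` and `truth_areas` filled in.
#' @export
#' @examples
#' pr <- default_profiles()[["diffuse_a"]]
#' img <- generate_micrograph(pr, side_px = 128, scale = 4.44, seed = 7)
#' img
generate_micrograph <- function(profile, side_px, scale = 0.74,
                                seed = profile$seed) {
  if (!inherits(profile, "porosity_profile"))
    stop("`profile` must be a porosity_profile", call. = FALSE)
  if (!is.numeric(side_px) || length(side_px) != 1L || side_px < 64)
    stop("`side_px` must be a single integer >= 64", call. = FALSE)
  stop_if_not_scalar_pos(scale, "scale")
  side_px <- as.integer(side_px)

  with_seed(seed, {
    n <- side_px
    canvas <- matrix(profile$wall_gray, n, n)
    mask <- matrix(0L, n, n)
    width_mm <- n * scale / 1000

    # rays: radial (vertical) thin bright lines flanked by darker walls
    n_rays <- round(profile$ray_lines_per_mm * width_mm)
    if (n_rays > 0) {
      ray_w <- max(1L, round(profile$ray_width / scale))
      ray_cols <- sort(sample.int(n, min(n_rays, n)))
      bright <- min(255, profile$wall_gray + 25)
      dark <- max(0, profile$wall_gray - 25)
      for (x0 in ray_cols) {
        core <- x0:min(n, x0 + ray_w - 1L)
        canvas[, core] <- bright
        if (x0 > 1L) canvas[, x0 - 1L] <- dark
        if (max(core) < n) canvas[, max(core) + 1L] <- dark
      }
    }

    # pore placement
    area_mm2 <- width_mm^2
    n_target <- round(profile$pores_per_mm2 * area_mm2)
    placed_x <- placed_y <- placed_r <- numeric(0)
    areas_px <- integer(0)
    next_id <- 0L
    if (n_target > 0) {
      mix <- profile$pore_mixture
      comp <- sample.int(nrow(mix), n_target, replace = TRUE,
                         prob = mix[, "weight"])
      diam <- rnorm(n_target, mix[comp, "mean"], mix[comp, "sd"])
      diam <- pmax(diam, 2 * scale)           # at least ~1 px radius
      is_ew <- mix[comp, "mean"] >= profile$earlywood_min_diameter
      ord <- order(diam, decreasing = TRUE)   # large pores placed first
      diam <- diam[ord]; is_ew <- is_ew[ord]

      if (profile$arrangement == "ring") {
        period_px <- profile$ring_period / scale
        band_px <- profile$earlywood_fraction * period_px
        phase <- runif(1, 0, period_px)
        n_bands <- ceiling(n / period_px) + 1L
      } else if (profile$arrangement == "radial") {
        wmean <- sum(profile$pore_mixture[, "mean"] *
                       profile$pore_mixture[, "weight"])
        spacing_px <- max(20, 4 * wmean) / scale
        n_files <- max(1L, floor(n / spacing_px))
        file_cols <- runif(1, 0, spacing_px) + (seq_len(n_files) - 1) * spacing_px
        file_cols <- file_cols[file_cols >= 1 & file_cols <= n]
        if (length(file_cols) == 0L) file_cols <- n / 2
      }

      for (i in seq_len(n_target)) {
        r_px <- diam[i] / (2 * scale)
        ratio <- runif(1, 1, 1.3)
        theta <- runif(1, 0, pi)
        r_eff <- r_px * sqrt(ratio)           # circumscribed radius
        done <- FALSE
        for (attempt in seq_len(1000L)) {
          if (profile$arrangement == "ring" && is_ew[i]) {
            band <- sample.int(n_bands, 1L) - 1L
            y <- phase + (band - 1L) * period_px + runif(1, 0, band_px)
            if (y < 1 || y > n) next
            x <- runif(1, 1, n)
          } else if (profile$arrangement == "radial") {
            x <- file_cols[sample.int(length(file_cols), 1L)]
            y <- runif(1, 1, n)
          } else {
            x <- runif(1, 1, n)
            y <- runif(1, 1, n)
          }
          if (length(placed_x) > 0) {
            d2 <- (placed_x - x)^2 + (placed_y - y)^2
            if (any(d2 < (placed_r + r_eff + 1)^2)) next
          }
          px <- ellipse_pixels(x, y, r_px, ratio, theta, n, n)
          if (length(px) == 0L) next
          next_id <- next_id + 1L
          canvas[px] <- profile$lumen_gray
          mask[px] <- next_id
          placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
          placed_r <- c(placed_r, r_eff)
          areas_px <- c(areas_px, length(px))
          done <- TRUE
          break
        }
        if (!done) next   # placement failed; pore skipped
      }
    }

    if (profile$noise_sd > 0)
      canvas <- canvas + rnorm(length(canvas), 0, profile$noise_sd)
    canvas <- matrix(pmin(255, pmax(0, round(canvas))), n, n)

    micrograph(canvas, scale = scale, label = profile$class_label,
               truth_mask = mask, truth_areas = areas_px * scale^2)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws `images_per_class` micrographs from each profile with per-image
#' seeds derived deterministically from `seed`, so a fixed seed reproduces
#' the identical dataset.
#'
#' @param profiles list of [porosity_profile()] with distinct class labels
#'   (at least 2).
#' @param images_per_class number of images per profile.
#' @param side_px image side in pixels.
#' @param scale micrometres per pixel.
#' @param seed integer master seed.
#' @return a list of [micrograph()] objects with labels and individual ids.
#' @export
generate_dataset <- function(profiles, images_per_class, side_px = 600,
                             scale = 0.74, seed = 1L) {
  if (length(profiles) < 2L)
    stop("at least two profiles are required", call. = FALSE)
  labels <- vapply(profiles, `[[`, "", "class_label")
  if (anyDuplicated(labels))
    stop("profiles must have distinct class labels", call. = FALSE)
  if (images_per_class < 1L)
    stop("`images_per_class` must be >= 1", call. = FALSE)
  out <- vector("list", length(profiles) * images_per_class)
  idx <- 0L
  for (ci in seq_along(profiles)) {
    for (ii in seq_len(images_per_class)) {
      idx <- idx + 1L
      img <- generate_micrograph(profiles[[ci]], side_px = side_px,
                                 scale = scale,
                                 seed = derive_seed(seed, ci, ii))
      img$individual_id <- sprintf("%s_%02d", labels[ci], ii)
      out[[idx]] <- img
    }
  }
  out
}

#' The default synthetic benchmark dataset
#'
#' The 18 default profiles rendered at 600 x 600 px and 4.44 um/px --
#' the field of view of a 3600 px, 0.74 um/px micrograph downscaled to
#' 600 px -- with a fixed generator seed, the configuration used by the
#' package's acceptance benchmarks.
#'
#' @param images_per_class images per class (default 30).
#' @param side_px image side (default 600).
#' @param scale micrometres per pixel (default `0.74 * 6`).
#' @param seed generator seed (default 42; fixed by convention).
#' @return list of micrographs.
#' @export
default_dataset <- function(images_per_class = 30, side_px = 600,
                            scale = 0.74 * 6, seed = 42L) {
  generate_dataset(default_profiles(), images_per_class = images_per_class,
                   side_px = side_px, scale = scale, seed = seed)
}
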