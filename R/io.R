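#' Write a micrograph to disk
#'
#' The pixel matrix is written as an 8-bit grayscale PNG (or a binary PGM
#' when the filename ends in `.pgm`).  If a ground-truth mask is present it
#' is written alongside as a 16-bit PGM label image (`<name>_mask.pgm`),
#' PGM being the plainest portable container for 16-bit labels.
#'
#' @param image a [micrograph()].
#' @param path output filename (`.png` or `.pgm`).
#' @param with_mask write the ground-truth mask sidecar if available.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path, with_mask = TRUE) {
  stopifnot(is_micrograph(image))
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    write_pgm(image$pixels, path, maxval = 255L)
  } else {
    png::writePNG(image$pixels / 255, target = path)
  }
  if (with_mask && !is.null(image$truth_mask)) {
    mask_path <- sub("\\.(png|pgm)$", "_mask.pgm", path, ignore.case = TRUE)
    write_pgm(image$truth_mask, mask_path, maxval = 65535L)
  }
  invisible(path)
}

#' Read a micrograph from disk
#'
#' Reads a PNG or PGM image, converts it to 8-bit grayscale if needed, and
#' attaches the given physical scale and label.
#'
#' @param path image file (`.png` or `.pgm`).
#' @param scale micrometres per pixel.
#' @param label optional class label.
#' @param individual_id optional specimen id.
#' @return a [micrograph()].
#' @export
read_micrograph <- function(path, scale, label = NULL, individual_id = NULL) {
  px <- if (grepl("\\.pgm$", path, ignore.case = TRUE)) read_pgm(path)
        else png::readPNG(path)
  micrograph(to_gray8(px), scale = scale, label = label,
             individual_id = individual_id)
}

# Minimal binary PGM (P5) writer/reader; 8-bit or 16-bit big-endian.
write_pgm <- function(m, path, maxval = 255L) {
  stopifnot(is.matrix(m), max(m) <= maxval, min(m) >= 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(m), nrow(m), maxval), con,
            eos = NULL)
  v <- as.integer(round(t(m)))          # row-major as PGM expects
  size <- if (maxval > 255L) 2L else 1L
  if (size == 2L && any(v > 32767L))
    stop("PGM writer supports label values up to 32767", call. = FALSE)
  writeBin(v, con, size = size, endian = "big")
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "P5")) stop("only binary (P5) PGM is supported", call. = FALSE)
  hdr <- integer(0)
  while (length(hdr) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    hdr <- c(hdr, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
  }
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  size <- if (maxval > 255L) 2L else 1L
  v <- readBin(con, "integer", n = w * h, size = size, signed = FALSE,
               endian = "big")
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a synthetic dataset to a directory
#'
#' Writes each micrograph as PNG plus its 16-bit PGM mask, and a
#' `manifest.csv` with `filename`, `class_label`, `individual_id`, `scale`.
#'
#' @param images list of [micrograph()] objects.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(images), function(i) {
    im <- images[[i]]
    fn <- sprintf("img_%04d.png", i)
    write_micrograph(im, file.path(dir, fn))
    data.frame(filename = fn, class_label = im$label %||% NA_character_,
               individual_id = im$individual_id %||% NA_character_,
               scale = im$scale)
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of [micrograph()] objects.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_micrograph(file.path(dir, manifest$filename[i]),
                    scale = manifest$scale[i],
                    label = manifest$class_label[i],
                    individual_id = manifest$individual_id[i]))
}

#' Write porosity profiles to a plain-text config file
#'
#' One Debian-control-format record per class; the mixture is encoded as
#' `mean:sd:weight` triplets separated by `;`.
#'
#' @param profiles list of [porosity_profile()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  recs <- lapply(profiles, function(p) {
    mix <- apply(p$pore_mixture, 1L, function(r)
      sprintf("%g:%g:%g", r[["mean"]], r[["sd"]], r[["weight"]]))
    c(class_label = p$class_label, arrangement = p$arrangement,
      pore_mixture = paste(mix, collapse = ";"),
      ring_period = if (!is.null(p$ring_period)) sprintf("%g", p$ring_period),
      earlywood_fraction = if (!is.null(p$earlywood_fraction))
        sprintf("%g", p$earlywood_fraction),
      pores_per_mm2 = sprintf("%g", p$pores_per_mm2),
      wall_gray = sprintf("%g", p$wall_gray),
      lumen_gray = sprintf("%g", p$lumen_gray),
      ray_lines_per_mm = sprintf("%g", p$ray_lines_per_mm),
      ray_width = sprintf("%g", p$ray_width),
      noise_sd = sprintf("%g", p$noise_sd),
      seed = sprintf("%d", p$seed),
      earlywood_min_diameter = sprintf("%g", p$earlywood_min_diameter))
  })
  fields <- unique(unlist(lapply(recs, names)))
  m <- do.call(rbind, lapply(recs, function(r) r[fields]))
  colnames(m) <- fields
  write.dcf(m, file = path)
  invisible(path)
}

#' Read porosity profiles from a plain-text config file
#' @param path file written by [write_profiles()] (or hand-edited in the
#'   same format).
#' @return named list of [porosity_profile()] objects.
#' @export
read_profiles <- function(path) {
  m <- read.dcf(path)
  num <- function(row, f, default = NULL) {
    if (!f %in% colnames(m) || is.na(row[[f]])) default
    else as.numeric(row[[f]])
  }
  out <- lapply(seq_len(nrow(m)), function(i) {
    row <- as.list(m[i, ])
    trip <- strsplit(strsplit(row$pore_mixture, ";")[[1]], ":")
    mix <- do.call(rbind, lapply(trip, as.numeric))
    porosity_profile(
      class_label = row$class_label, arrangement = row$arrangement,
      pore_mixture = data.frame(mean = mix[, 1], sd = mix[, 2], weight = mix[, 3]),
      ring_period = num(row, "ring_period"),
      earlywood_fraction = num(row, "earlywood_fraction"),
      pores_per_mm2 = num(row, "pores_per_mm2"),
      wall_gray = num(row, "wall_gray", 120),
      lumen_gray = num(row, "lumen_gray", 230),
      ray_lines_per_mm = num(row, "ray_lines_per_mm", 0.8),
      ray_width = num(row, "ray_width", 12),
      noise_sd = num(row, "noise_sd", 10),
      seed = as.integer(num(row, "seed", 1)),
      earlywood_min_diameter = num(row, "earlywood_min_diameter", 100))
  })
  names(out) <- vapply(out, `[[`, "", "class_label")
  out
}

#' Write a feature table as CSV
#'
#' Columns: `image_id`, `label`, `group_id`, then one column per feature.
#'
#' @param table a [feature_table()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(
    image_id = attr(table, "image_ids") %||% seq_len(nrow(table)),
    label = ft_labels(table),
    group_id = attr(table, "group_ids") %||% NA_character_,
    unclass(table), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(as.matrix(df[, -(1:3), drop = FALSE]), labels = df$label,
                group_ids = df$group_id, image_ids = df$image_id)
}
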