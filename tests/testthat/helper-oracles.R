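# Independent oracles used to cross-check the implementation.

# Brute-force flood-fill labelling (iterative stack), 4- or 8-connectivity.
# Returns list(n, areas) with areas sorted by first-pixel scan order.
flood_fill_oracle <- function(mask, connectivity = 4) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  areas <- integer(0)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (t in seq_len(nrow(nb))) {
        r <- p[1] + nb[t, 1]; c <- p[2] + nb[t, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    areas <- c(areas, area)
  }
  list(n = length(areas), areas = areas)
}

# Exhaustive O(n^3) Ward linkage from raw points.  At each step merges the
# pair whose within-cluster sum of squares increases least; heights follow
# the sqrt(2 * delta-ESS) convention of Euclidean Ward linkage, matching
# hclust(method = "ward.D2").  Returns merge sets (leaf index sets per
# merge) and heights.
ward_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)  # members per active cluster
  merges <- list(); heights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      ma <- colMeans(x[clusters[[a]], , drop = FALSE])
      mb <- colMeans(x[clusters[[b]], , drop = FALSE])
      na <- length(clusters[[a]]); nb_ <- length(clusters[[b]])
      d <- na * nb_ / (na + nb_) * sum((ma - mb)^2)
      if (is.null(best) || d < best$d) best <- list(a = a, b = b, d = d)
    }
    merges[[step]] <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    heights[step] <- sqrt(2 * best$d)
    clusters[[best$a]] <- merges[[step]]
    clusters[[best$b]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Leaf sets per merge of an hclust-style merge matrix.
merge_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(grab(merge[i, 1]), grab(merge[i, 2])))
  }
  sets
}

# Paint a filled disc on a matrix (used to build SIFT test scenes).
draw_disc <- function(px, cx, cy, r, value) {
  ys <- pmax(1, floor(cy - r)):pmin(nrow(px), ceiling(cy + r))
  xs <- pmax(1, floor(cx - r)):pmin(ncol(px), ceiling(cx + r))
  for (yy in ys) for (xx in xs)
    if ((xx - cx)^2 + (yy - cy)^2 <= r^2) px[yy, xx] <- value
  px
}

# Small profile helpers for cheap test images.
test_profile <- function(label = "t", arrangement = "diffuse",
                         mean = 60, sd = 5, weight = 1,
                         pores_per_mm2 = 30, noise_sd = 0,
                         ray_lines_per_mm = 0, ...) {
  porosity_profile(label, arrangement,
                   data.frame(mean = mean, sd = sd, weight = weight),
                   pores_per_mm2 = pores_per_mm2, noise_sd = noise_sd,
                   ray_lines_per_mm = ray_lines_per_mm, ...)
}
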