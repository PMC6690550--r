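#' Pool keypoint descriptors across images
#'
#' Stacks the descriptors of many images into one matrix with per-row
#' provenance (image id, class label, position and scale), the input of the
#' visual-word atlas.
#'
#' @param keypoint_sets list of `sift_keypoints` objects (see
#'   [detect_keypoints()]).
#' @param image_ids identifier per image.
#' @param labels class label per image.
#' @return an object of class `keypoint_pool`: list with `descriptors`
#'   (N x 128) and `provenance` (data frame with `image_id`, `label`, `x`,
#'   `y`, `scale`).
#' @export
keypoint_pool <- function(keypoint_sets, image_ids, labels) {
  stopifnot(length(keypoint_sets) == length(image_ids),
            length(keypoint_sets) == length(labels))
  descs <- do.call(rbind, lapply(keypoint_sets, `[[`, "descriptors"))
  prov <- do.call(rbind, lapply(seq_along(keypoint_sets), function(i) {
    kp <- keypoint_sets[[i]]$keypoints
    if (nrow(kp) == 0L) return(NULL)
    data.frame(image_id = image_ids[i], label = labels[i],
               x = kp$x, y = kp$y, scale = kp$scale)
  }))
  if (is.null(descs) || nrow(descs) == 0L)
    stop("the pool contains no keypoints", call. = FALSE)
  structure(list(descriptors = descs, provenance = prov),
            class = "keypoint_pool")
}

#' @exportS3Method base::print
print.keypoint_pool <- function(x, ...) {
  cat(sprintf("<keypoint_pool> %d keypoints from %d images, %d classes\n",
              nrow(x$descriptors), length(unique(x$provenance$image_id)),
              length(unique(x$provenance$label))))
  invisible(x)
}

# k-means++ seeding followed by Lloyd iterations; empty clusters are
# re-seeded by splitting the largest cluster at its farthest member.
kmeans_lloyd <- function(X, k, max_iter = 100L) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2min <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (k >= 2L) for (j in 2L:k) {
    pr <- if (sum(d2min) > 0) d2min / sum(d2min) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = pr), ]
    d2min <- pmin(d2min, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  xsq <- rowSums(X^2)
  assign_step <- function(centers) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
    list(cl = max.col(-d2, ties.method = "first"),
         d2 = pmax(d2, 0))
  }
  cl_old <- integer(n)
  for (it in seq_len(max_iter)) {
    a <- assign_step(centers)
    cl <- a$cl
    for (j in seq_len(k)) {
      if (!any(cl == j)) {     # empty cluster: split the largest
        big <- which.max(tabulate(cl, nbins = k))
        members <- which(cl == big)
        far <- members[which.max(a$d2[cbind(members, big)])]
        cl[far] <- j
        message(sprintf("k-means: empty cluster %d re-seeded from cluster %d", j, big))
      }
    }
    centers <- rowsum(X, cl) / as.vector(tabulate(cl, nbins = k))
    if (identical(cl, cl_old)) break
    cl_old <- cl
  }
  a <- assign_step(centers)
  list(centers = centers, cluster = a$cl,
       tot_withinss = sum(a$d2[cbind(seq_len(n), a$cl)]))
}

#' Build a keypoint atlas (visual-word vocabulary)
#'
#' Clusters pooled descriptors with k-means (k-means++ seeding, several
#' restarts, best objective kept) into `k` visual words, then groups the
#' `k` centroids into `n_subgroups` by Ward clustering of the centroid
#' coordinates.  Deterministic for a fixed seed.
#'
#' @param pool a [keypoint_pool()].
#' @param k number of clusters (default 18).
#' @param n_subgroups number of centroid subgroups (default 5).
#' @param seed integer seed.
#' @param n_restarts independent k-means restarts (default 10).
#' @param max_pool optional memory cap: pools larger than this are uniformly
#'   subsampled to `max_pool` keypoints before fitting (assignments are
#'   still computed for the full pool).
#' @return an `atlas_model`: list with `centers` (k x 128), `assignments`
#'   (per pooled keypoint), `subgroups` (length-k map to 1..n_subgroups),
#'   `subgroup_linkage` (a `dendrogram_model` of the centroids), and
#'   `tot_withinss`.
#' @export
build_atlas <- function(pool, k = 18L, n_subgroups = 5L, seed = 1L,
                        n_restarts = 10L, max_pool = NULL) {
  X <- pool$descriptors
  if (nrow(X) < k)
    stop("pool smaller than the number of clusters", call. = FALSE)
  if (k < n_subgroups)
    stop("`k` must be at least `n_subgroups`", call. = FALSE)
  with_seed(seed, {
    fit_X <- X
    if (!is.null(max_pool) && nrow(X) > max_pool)
      fit_X <- X[sample.int(nrow(X), max_pool), , drop = FALSE]
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_lloyd(fit_X, k)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
    centers <- best$centers
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
    assignments <- max.col(-d2, ties.method = "first")
    if (k > 1L) {
      link <- ward_cluster(centers, labels = sprintf("word_%02d", seq_len(k)))
      subgroups <- unname(cutree(link$hclust, k = n_subgroups))
    } else {
      link <- NULL
      subgroups <- 1L
    }
    structure(list(centers = centers, assignments = assignments,
                   subgroups = subgroups, subgroup_linkage = link,
                   k = as.integer(k), n_subgroups = as.integer(n_subgroups),
                   tot_withinss = best$tot_withinss, seed = as.integer(seed)),
              class = "atlas_model")
  })
}

#' @exportS3Method base::print
print.atlas_model <- function(x, ...) {
  cat(sprintf("<atlas_model> k = %d visual words in %d subgroups, objective %.4g\n",
              x$k, x$n_subgroups, x$tot_withinss))
  invisible(x)
}

#' Per-class composition ratios of the visual words
#'
#' For each class, the proportion of its keypoints assigned to each of the
#' `k` clusters (rows sum to 1), plus the mean number of keypoints per
#' image of that class.
#'
#' @param model an `atlas_model` fitted on `pool`.
#' @param pool the [keypoint_pool()] the model was fitted on.
#' @return a `composition_matrix`: list with `ratios` (classes x k matrix)
#'   and `mean_keypoints` (per-class mean keypoints per image).
#' @export
composition_ratios <- function(model, pool) {
  if (length(model$assignments) != nrow(pool$descriptors))
    stop("model was not fitted on this pool", call. = FALSE)
  lab <- pool$provenance$label
  if (any(base::table(lab) < 1L)) stop("class with zero keypoints", call. = FALSE)
  counts <- base::table(factor(lab), factor(model$assignments,
                                            levels = seq_len(model$k)))
  ratios <- unclass(counts / rowSums(counts))
  imgs <- tapply(pool$provenance$image_id, lab,
                 function(v) length(unique(v)))
  mean_kp <- rowSums(counts) / as.vector(imgs[rownames(counts)])
  structure(list(ratios = ratios, mean_keypoints = mean_kp),
            class = "composition_matrix")
}

#' @exportS3Method base::print
print.composition_matrix <- function(x, ...) {
  cat(sprintf("<composition_matrix> %d classes x %d visual words\n",
              nrow(x$ratios), ncol(x$ratios)))
  invisible(x)
}

#' Overlay the keypoints of one visual word on an image
#'
#' Draws circle outlines (radius proportional to the keypoint scale) at the
#' positions of the keypoints of `cluster_id` detected in `image_id`; all
#' other pixels are left untouched.
#'
#' @param image the [micrograph()] the keypoints were detected in.
#' @param model an `atlas_model`.
#' @param pool the [keypoint_pool()] the model was fitted on.
#' @param cluster_id visual word index in `1..k`.
#' @param image_id the image's identifier within the pool provenance.
#' @param marker_gray intensity of the drawn circles (default 255).
#' @return a matrix of intensities with the markers burnt in.
#' @export
overlay_cluster <- function(image, model, pool, cluster_id, image_id,
                            marker_gray = 255) {
  if (!cluster_id %in% seq_len(model$k))
    stop("unknown cluster id", call. = FALSE)
  if (!image_id %in% pool$provenance$image_id)
    stop("image not present in the pool", call. = FALSE)
  px <- as_pixels(image)
  sel <- pool$provenance$image_id == image_id & model$assignments == cluster_id
  kp <- pool$provenance[sel, , drop = FALSE]
  h <- nrow(px); w <- ncol(px)
  for (i in seq_len(nrow(kp))) {
    r <- max(2, round(2 * kp$scale[i]))
    th <- seq(0, 2 * pi, length.out = max(16L, round(2 * pi * r)))
    xs <- round(kp$x[i] + r * cos(th))
    ys <- round(kp$y[i] + r * sin(th))
    ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
    px[cbind(ys[ok], xs[ok])] <- marker_gray
  }
  px
}
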