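# Build a small pool of synthetic "keypoints" with controllable structure.
fake_pool <- function(blobs, per_blob, labels = NULL, spread = 0.02,
                      seed = 1) {
  set.seed(seed)
  centres <- matrix(runif(blobs * 128), blobs, 128)
  descs <- do.call(rbind, lapply(seq_len(blobs), function(b)
    sweep(matrix(rnorm(per_blob * 128, 0, spread), per_blob, 128), 2L,
          centres[b, ], "+")))
  n <- blobs * per_blob
  prov <- data.frame(
    image_id = rep_len(sprintf("img%d", 1:4), n),
    label = labels %||% rep(sprintf("class%d", seq_len(blobs)),
                            each = per_blob),
    x = runif(n, 1, 100), y = runif(n, 1, 100), scale = runif(n, 1, 4))
  structure(list(descriptors = descs, provenance = prov,
                 blob = rep(seq_len(blobs), each = per_blob)),
            class = "keypoint_pool")
}

test_that("18 distinct descriptors with k = 18 get singleton clusters", {
  pool <- fake_pool(18, 1, spread = 0)
  model <- build_atlas(pool, k = 18, n_subgroups = 5, seed = 2)
  expect_lt(model$tot_withinss, 1e-12)
  expect_identical(sort(unique(model$assignments)), 1:18)
})

test_that("duplicating every pool row leaves the centroid set unchanged", {
  pool <- fake_pool(3, 30, spread = 0.01, seed = 4)
  dup <- pool
  dup$descriptors <- rbind(pool$descriptors, pool$descriptors)
  dup$provenance <- rbind(pool$provenance, pool$provenance)
  m1 <- build_atlas(pool, k = 3, n_subgroups = 2, seed = 5)
  m2 <- build_atlas(dup, k = 3, n_subgroups = 2, seed = 5)
  ord <- function(m) m$centers[order(m$centers[, 1]), ]
  expect_equal(ord(m1), ord(m2), tolerance = 1e-8)
})

test_that("well-separated blobs are recovered exactly", {
  pool <- fake_pool(3, 40, spread = 0.01, seed = 6)
  model <- build_atlas(pool, k = 3, n_subgroups = 3, seed = 7)
  # partition must match the generating blobs (up to cluster renaming)
  tab <- table(pool$blob, model$assignments)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("assignments are the argmin over centroid distances", {
  pool <- fake_pool(4, 25, spread = 0.3, seed = 8)
  model <- build_atlas(pool, k = 6, n_subgroups = 3, seed = 9)
  d2 <- outer(rowSums(pool$descriptors^2), rowSums(model$centers^2), "+") -
    2 * tcrossprod(pool$descriptors, model$centers)
  expect_identical(model$assignments, max.col(-d2, ties.method = "first"))
})

test_that("atlas fitting is deterministic and validates inputs", {
  pool <- fake_pool(3, 20, seed = 10)
  m1 <- build_atlas(pool, k = 5, n_subgroups = 3, seed = 11)
  m2 <- build_atlas(pool, k = 5, n_subgroups = 3, seed = 11)
  expect_identical(m1$centers, m2$centers)
  expect_identical(m1$assignments, m2$assignments)
  expect_error(build_atlas(pool, k = 100, seed = 1), "smaller")
  expect_error(build_atlas(pool, k = 3, n_subgroups = 5, seed = 1),
               "at least")
})

test_that("the subgroup map covers every visual word exactly once", {
  pool <- fake_pool(6, 30, spread = 0.2, seed = 12)
  model <- build_atlas(pool, k = 18, n_subgroups = 5, seed = 13)
  expect_length(model$subgroups, 18L)
  expect_identical(sort(unique(model$subgroups)), 1:5)  # 5 non-empty groups
})

test_that("composition rows are probability vectors with sane counts", {
  pool <- fake_pool(2, 50, labels = rep(c("sp1", "sp2"), each = 50),
                    spread = 0.01, seed = 14)
  model <- build_atlas(pool, k = 2, n_subgroups = 2, seed = 15)
  comp <- composition_ratios(model, pool)
  expect_equal(unname(rowSums(comp$ratios)), c(1, 1), tolerance = 1e-9)
  expect_true(all(comp$ratios >= 0))
  # disjoint descriptor blobs per class -> disjoint cluster support
  expect_true(all(colSums(comp$ratios > 0) == 1))
  # 100 keypoints over 4 provenance images, evenly interleaved
  expect_equal(sum(comp$mean_keypoints * c(2, 2)), 100 / 2)
})

test_that("single class and single cluster give proportion 1", {
  pool <- fake_pool(1, 30, labels = rep("only", 30), seed = 16)
  model <- build_atlas(pool, k = 1, n_subgroups = 1, seed = 17)
  comp <- composition_ratios(model, pool)
  expect_equal(unname(comp$ratios[1, 1]), 1)
})

test_that("overlays mark exactly the requested cluster's keypoints", {
  pr <- test_profile(mean = 60, sd = 6, pores_per_mm2 = 40, noise_sd = 5)
  img <- generate_micrograph(pr, side_px = 150, scale = 4.44, seed = 18)
  img$label <- "a"
  kps <- detect_keypoints(img)
  pool <- keypoint_pool(list(kps), image_ids = "im1", labels = "a")
  model <- build_atlas(pool, k = 4, n_subgroups = 2, seed = 19)

  # a cluster with no keypoints in the image leaves pixels untouched
  empty_model <- model
  empty_model$assignments <- rep(1L, length(model$assignments))
  out <- overlay_cluster(img, empty_model, pool, cluster_id = 2,
                         image_id = "im1")
  expect_identical(out, img$pixels)

  # union of all clusters equals the whole-keypoint-set overlay
  full <- img$pixels
  for (cid in 1:4)
    full[overlay_cluster(img, model, pool, cid, "im1") != img$pixels] <- 255
  whole_model <- model
  whole_model$assignments <- rep(1L, length(model$assignments))
  whole <- overlay_cluster(img, whole_model, pool, 1, "im1")
  expect_identical(full != img$pixels, whole != img$pixels)

  expect_error(overlay_cluster(img, model, pool, 99, "im1"), "cluster")
  expect_error(overlay_cluster(img, model, pool, 1, "nope"), "not present")
})

test_that("single keypoint overlay is centred within a pixel", {
  img <- micrograph(matrix(100, 80, 80), scale = 1)
  pool <- structure(list(
    descriptors = matrix(0, 1, 128),
    provenance = data.frame(image_id = "im1", label = "a", x = 40.2,
                            y = 33.7, scale = 2)), class = "keypoint_pool")
  model <- list(k = 1L, assignments = 1L, centers = matrix(0, 1, 128))
  class(model) <- "atlas_model"
  out <- overlay_cluster(img, model, pool, 1, "im1")
  marked <- which(out != img$pixels, arr.ind = TRUE)
  expect_gt(nrow(marked), 0)
  cx <- mean(range(marked[, "col"])); cy <- mean(range(marked[, "row"]))
  expect_lt(abs(cx - 40.2), 1)
  expect_lt(abs(cy - 33.7), 1)
})
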