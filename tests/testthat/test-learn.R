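rand_table <- function(n_per_class, classes, p = 6, sep = 6, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    mu <- rnorm(p) * sep
    sweep(matrix(rnorm(n_per_class * p), n_per_class, p), 2L, mu, "+")
  }))
  feature_table(x, labels = rep(classes, each = n_per_class))
}

test_that("the reduced dimension is always C - 1", {
  t18 <- rand_table(4, sprintf("c%02d", 1:18), p = 40)
  expect_identical(ncol(lda_reduce(t18)), 17L)
  t2 <- rand_table(5, c("a", "b"))
  expect_identical(ncol(lda_reduce(t2)), 1L)
  expect_error(lda_reduce(feature_table(matrix(rnorm(6), 3, 2),
                                        labels = c("a", "a", "b"))),
               "at least 2 rows")
})

test_that("two-class discriminant matches the closed-form Fisher direction", {
  set.seed(42)
  n <- 200; p <- 5
  x1 <- matrix(rnorm(n * p), n, p)
  x2 <- matrix(rnorm(n * p), n, p); x2[, 2] <- x2[, 2] + 8
  tab <- feature_table(rbind(x1, x2), labels = rep(c("a", "b"), each = n))
  red <- lda_reduce(tab)
  v <- attr(red, "projection")$rotation[, 1]
  # independent closed form: Sw^-1 (mu1 - mu2)
  Sw <- crossprod(sweep(x1, 2, colMeans(x1))) + crossprod(sweep(x2, 2, colMeans(x2)))
  w <- solve(Sw, colMeans(x1) - colMeans(x2))
  cosine <- abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2))
  expect_gt(cosine, 0.99)
  # and the separating axis itself
  e2 <- c(0, 1, 0, 0, 0)
  expect_gt(abs(sum(v * e2)) / sqrt(sum(v^2)), 0.99)
})

test_that("discriminant axes agree with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  tab <- rand_table(12, c("a", "b", "c"), p = 4, sep = 2, seed = 3)
  red <- lda_reduce(tab)
  V <- attr(red, "projection")$rotation
  m <- MASS::lda(unclass(tab), grouping = factor(attr(tab, "labels")))
  for (j in 1:2) {
    cosine <- abs(sum(V[, j] * m$scaling[, j])) /
      sqrt(sum(V[, j]^2) * sum(m$scaling[, j]^2))
    expect_gt(cosine, 0.999)
  }
})

test_that("singular within-class scatter falls back to a logged ridge", {
  x <- cbind(rnorm(20), 0)  # constant second feature
  tab <- feature_table(x, labels = rep(c("a", "b"), 10))
  expect_message(red <- lda_reduce(tab), "ridge")
  expect_identical(ncol(red), 1L)
})

test_that("classifier evaluation: separable, indistinguishable and null", {
  # far-separated classes: every classifier perfect
  sep <- rand_table(15, c("a", "b", "c"), p = 4, sep = 12, seed = 5)
  rep_sep <- evaluate(sep, eval_scheme(repeats = 3, seed = 1))
  expect_true(all(rep_sep$mean == 1))

  # identical feature distributions: accuracy near chance (1/2)
  set.seed(8)
  same <- feature_table(matrix(rnorm(120 * 3), 120, 3),
                        labels = rep(c("a", "b"), each = 60))
  rep_same <- evaluate(same, eval_scheme(repeats = 10, seed = 2),
                       classifiers = "knn9")
  n_test <- 24
  expect_lt(abs(rep_same$mean[["knn9"]] - 0.5), 3 * sqrt(0.25 / n_test))

  # permutation null for a multi-class table
  multi <- rand_table(20, c("a", "b", "c", "d"), p = 4, sep = 10, seed = 6)
  set.seed(9)
  perm <- feature_table(unclass(multi), labels = sample(attr(multi, "labels")))
  rep_null <- evaluate(perm, eval_scheme(repeats = 10, seed = 3))
  p0 <- 1 / 4; n_test <- 16
  for (cl in names(rep_null$mean))
    expect_lt(abs(rep_null$mean[[cl]] - p0), 3 * sqrt(p0 * (1 - p0) / n_test))
})

test_that("accuracy reports are structurally sound", {
  tab <- rand_table(10, c("a", "b", "c"), sep = 8, seed = 11)
  rep_ <- evaluate(tab, eval_scheme(repeats = 4, seed = 7))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  expect_identical(dim(rep_$accuracy), c(4L, 3L))
  for (cm in rep_$confusion) {
    # row sums equal summed per-class test counts: 2 per class per repeat
    expect_equal(unname(rowSums(cm)), rep(2 * 4, 3))
  }
  # global-scope reduction reproduces the feed-forward order
  rep_g <- evaluate(tab, eval_scheme(repeats = 4, seed = 7,
                                     lda_scope = "global"))
  expect_true(all(rep_g$mean == 1))
})

test_that("stratified splits keep every class in training", {
  tab <- rand_table(5, c("a", "b", "c"), seed = 13)
  for (r in 1:20) {
    set.seed(r)
    test <- xylovision:::split_indices(attr(tab, "labels"), 0.2, TRUE)
    expect_setequal(unique(attr(tab, "labels")[-test]), c("a", "b", "c"))
    expect_length(test, 3L)
  }
})

test_that("Ward clustering merges nearest clusters first", {
  m <- ward_cluster(matrix(c(0, 1, 10), 3, 1), labels = c("p", "q", "r"))
  expect_identical(sort(m$merge[1, ]), c(-2L, -1L))
  m4 <- ward_cluster(matrix(rnorm(8), 4, 2))
  expect_identical(nrow(m4$merge), 3L)
  expect_true(all(diff(m4$height) >= -1e-12))
  expect_error(ward_cluster(matrix(0, 1, 2)), "two rows")
})

test_that("Ward merge sequence matches the exhaustive O(n^3) oracle", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(20 * 3), 20, 3)
    model <- ward_cluster(x)
    oracle <- ward_oracle(x)
    expect_identical(merge_sets(model$merge), oracle$merges)
    expect_equal(model$height, oracle$heights, tolerance = 1e-8)
  }
})

test_that("class dendrograms have one leaf per class", {
  tab <- rand_table(6, c("a", "b", "c", "d"), sep = 5, seed = 21)
  red <- lda_reduce(tab)
  cd <- class_dendrogram(red)
  expect_setequal(cd$labels, c("a", "b", "c", "d"))
  nw <- export_newick(cd)
  expect_match(nw, "^\\(")
  expect_true(all(vapply(c("a", "b", "c", "d"), grepl, TRUE, x = nw)))
})

test_that("a degenerate resolution sweep equals a direct evaluation", {
  prs <- list(test_profile("a", mean = 30, sd = 3, pores_per_mm2 = 60,
                           noise_sd = 5),
              test_profile("b", mean = 80, sd = 6, pores_per_mm2 = 25,
                           noise_sd = 5))
  imgs <- generate_dataset(prs, images_per_class = 6, side_px = 128,
                           scale = 4.44, seed = 31)
  sch <- eval_scheme(repeats = 3, seed = 4)
  sw <- resolution_sweep(imgs, sizes = 128, features = "pores", scheme = sch,
                         classifiers = "knn9")
  direct <- evaluate(pore_feature_table(imgs), sch, classifiers = "knn9")
  expect_equal(sw$reports[["128"]]$accuracy, direct$accuracy)
  expect_identical(nrow(sw$summary), 1L)

  sw2 <- resolution_sweep(imgs, sizes = c(128, 64), features = "pores",
                          scheme = sch, classifiers = "knn9")
  expect_identical(sort(unique(sw2$summary$size)), c(64L, 128L))
})

test_that("classes separated only by fine structure collapse at low size", {
  # pores of 3 px vs 5 px diameter at full size; both vanish at 16 px
  prs <- list(test_profile("fine", mean = 12, sd = 1, pores_per_mm2 = 250,
                           noise_sd = 0),
              test_profile("coarse", mean = 20, sd = 1.5, pores_per_mm2 = 90,
                           noise_sd = 0))
  imgs <- generate_dataset(prs, images_per_class = 8, side_px = 160,
                           scale = 4, seed = 41)
  sch <- eval_scheme(repeats = 5, seed = 6)
  sw <- resolution_sweep(imgs, sizes = c(160, 16), features = "pores",
                         scheme = sch, classifiers = "knn9")
  full <- subset(sw$summary, size == 160)$mean_accuracy
  tiny <- subset(sw$summary, size == 16)$mean_accuracy
  expect_gte(full, 0.9)
  expect_lte(tiny, 0.75)
})

test_that("group-aware splits never divide a specimen", {
  tab <- rand_table(12, c("a", "b"), sep = 8, seed = 17)
  tab <- feature_table(unclass(tab), labels = attr(tab, "labels"),
                       group_ids = rep(sprintf("g%d", 1:8), each = 3))
  for (r in 1:10) {
    set.seed(r)
    test <- xylovision:::split_indices(attr(tab, "labels"), 0.25, TRUE,
                                       group_ids = attr(tab, "group_ids"))
    g_test <- unique(attr(tab, "group_ids")[test])
    g_train <- unique(attr(tab, "group_ids")[-test])
    expect_length(intersect(g_test, g_train), 0L)
  }
  rep_ <- evaluate(tab, eval_scheme(repeats = 2, seed = 3, group_aware = TRUE),
                   classifiers = "knn9")
  expect_true(all(rep_$accuracy >= 0))
})
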