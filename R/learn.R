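#' Feature table
#'
#' Per-image feature vectors with class labels, the common currency of the
#' reduction, classification and clustering steps.
#'
#' @param x numeric matrix, one row per image.
#' @param labels class label per row (>= 2 distinct values).
#' @param group_ids optional specimen identifier per row.
#' @param image_ids optional image identifier per row.
#' @return an object of class `feature_table` (a matrix with attributes
#'   `labels`, `group_ids`, `image_ids`).
#' @export
feature_table <- function(x, labels, group_ids = NULL, image_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("features must be numeric with no missing values", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("one label per row is required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("at least two distinct labels are required", call. = FALSE)
  structure(x, labels = labels,
            group_ids = if (!is.null(group_ids)) as.character(group_ids),
            image_ids = image_ids,
            class = c("feature_table", class(x)))
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d images x %d features, %d classes\n",
              nrow(x), ncol(x), length(unique(attr(x, "labels")))))
  invisible(x)
}

ft_labels <- function(x) attr(x, "labels")

ft_subset <- function(x, i) {
  feature_table(unclass(x)[i, , drop = FALSE], labels = ft_labels(x)[i],
                group_ids = attr(x, "group_ids")[i],
                image_ids = attr(x, "image_ids")[i])
}

#' Fisher linear discriminant reduction
#'
#' Fits the Fisher discriminant projection on a training table and applies
#' it to another table (by default the training table itself), reducing the
#' features to exactly `C - 1` dimensions for `C` training classes.  The
#' projection maximises between-class over within-class scatter; discriminant
#' axes are normalised to unit within-class scatter.  A singular or
#' ill-conditioned within-class scatter triggers a small ridge
#' (shrinkage towards the identity), reported via a message.
#'
#' @param train a [feature_table()] with at least 2 rows per class.
#' @param apply_to table whose rows are projected (defaults to `train`).
#' @return a `reduced_features` object: a [feature_table()] with `C - 1`
#'   columns and attribute `projection` (list with `rotation`, `center`,
#'   `class_levels`).
#' @export
lda_reduce <- function(train, apply_to = train) {
  X <- unclass(train)
  y <- factor(ft_labels(train))
  C <- nlevels(y)
  p <- ncol(X)
  if (any(table(y) < 2L))
    stop("every training class needs at least 2 rows", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  class_means <- rowsum(Xc, y) / as.vector(table(y))
  Sw <- crossprod(Xc - class_means[y, , drop = FALSE])
  Sb <- crossprod(class_means * sqrt(as.vector(table(y))))
  # ridge fallback for singular / ill-conditioned within-class scatter
  lambda <- 0
  ok <- FALSE
  R <- try(chol(Sw), silent = TRUE)
  if (!inherits(R, "try-error")) {
    d <- diag(R)
    ok <- all(d > 0) && (min(d) / max(d))^2 > 1e-12
  }
  if (!ok) {
    lambda <- 1e-4 * mean(diag(Sw)) + 1e-12
    message(sprintf("within-class scatter singular; applying ridge %.3g", lambda))
    R <- chol(Sw + lambda * diag(p))
  }
  iR <- backsolve(R, diag(p))
  M <- crossprod(iR, Sb %*% iR)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ndim <- min(C - 1L, p)   # C-1 whenever the feature space allows it
  if (ndim < C - 1L)
    message(sprintf("feature dimension %d < classes - 1; reducing to %d", p, ndim))
  V <- iR %*% eig$vectors[, seq_len(ndim), drop = FALSE]
  V <- V * sqrt(nrow(X) - C)   # unit pooled within-class covariance per axis
  proj <- list(rotation = V, center = mu, class_levels = levels(y),
               eigenvalues = eig$values[seq_len(ndim)], ridge = lambda)
  Z <- sweep(unclass(apply_to), 2L, mu) %*% V
  colnames(Z) <- sprintf("LD%d", seq_len(ncol(Z)))
  out <- feature_table(Z, labels = ft_labels(apply_to),
                       group_ids = attr(apply_to, "group_ids"),
                       image_ids = attr(apply_to, "image_ids"))
  attr(out, "projection") <- proj
  class(out) <- c("reduced_features", class(out))
  out
}

#' Project new data with a fitted discriminant
#' @param object a `reduced_features` object returned by [lda_reduce()].
#' @param newdata a matrix or [feature_table()].
#' @param ... unused.
#' @return matrix of discriminant coordinates.
#' @export
predict.reduced_features <- function(object, newdata, ...) {
  pr <- attr(object, "projection")
  sweep(as.matrix(unclass(newdata)), 2L, pr$center) %*% pr$rotation
}

# ---- classifiers ----------------------------------------------------------

# k-nearest-neighbour vote; distance ties resolved by smallest training
# index (stable order), vote ties by smallest class index.
knn_predict <- function(train_x, train_y, test_x, k = 9L) {
  train_y <- factor(train_y)
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  lv <- levels(train_y)
  idx <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  pred <- apply(matrix(as.integer(train_y)[idx], nrow = k), 2L,
                function(v) which.max(tabulate(v, nbins = length(lv))))
  factor(lv[pred], levels = lv)
}

# Multinomial logistic regression, L2 penalty matching a "C = 1" ridge.
# glmnet's multinomial solver needs a decreasing lambda path, so we fit a
# short path ending at the target penalty and predict there.
logistic_fit <- function(train_x, train_y) {
  y <- factor(train_y)
  target <- 1 / nrow(train_x)
  # warm-started path from glmnet's own lambda_max down to the target
  f0 <- glmnet::glmnet(train_x, y, family = "multinomial", alpha = 0,
                       standardize = FALSE, nlambda = 30)
  path <- f0$lambda[f0$lambda > target]
  lo <- if (length(path)) min(path) else target * 100
  path <- c(path, exp(seq(log(lo), log(target), length.out = 10L))[-1])
  fit <- glmnet::glmnet(train_x, y, family = "multinomial", alpha = 0,
                        standardize = FALSE, lambda = path)
  fit$target_lambda <- target
  fit
}

logistic_predict <- function(fit, test_x) {
  p <- predict(fit, newx = as.matrix(test_x), type = "class",
               s = fit$target_lambda)
  factor(as.character(p), levels = fit$classnames)
}

# Linear SVM by dual coordinate descent (L2-regularised hinge loss,
# one-vs-rest, C = 1, bias handled via an augmented regularised intercept).
svm_binary <- function(X, y01, C = 1, max_epoch = 200L, tol = 1e-4) {
  y <- ifelse(y01, 1, -1)
  n <- nrow(X)
  Q <- rowSums(X^2)
  w <- numeric(ncol(X))
  alpha <- numeric(n)
  for (ep in seq_len(max_epoch)) {
    max_pg <- 0
    ord <- sample.int(n)
    for (i in ord) {
      G <- y[i] * sum(w * X[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(G, 0) else if (alpha[i] >= C) max(G, 0) else G
      if (abs(pg) > 1e-12) {
        max_pg <- max(max_pg, abs(pg))
        a_new <- min(max(alpha[i] - G / Q[i], 0), C)
        w <- w + (a_new - alpha[i]) * y[i] * X[i, ]
        alpha[i] <- a_new
      }
    }
    if (max_pg < tol) break
  }
  w
}

svm_fit <- function(train_x, train_y, C = 1) {
  train_y <- factor(train_y)
  Xa <- cbind(train_x, bias = 1)
  W <- vapply(levels(train_y),
              function(lv) svm_binary(Xa, train_y == lv, C = C),
              numeric(ncol(Xa)))
  list(W = W, levels = levels(train_y))
}

svm_predict <- function(fit, test_x) {
  scores <- cbind(as.matrix(test_x), bias = 1) %*% fit$W
  factor(fit$levels[max.col(scores, ties.method = "first")],
         levels = fit$levels)
}

# ---- evaluation -----------------------------------------------------------

#' Evaluation scheme for repeated train/test splits
#'
#' @param test_fraction fraction of rows held out per repeat (default 0.2,
#'   i.e. a 1:4 test:training ratio).
#' @param repeats number of random splits (default 10).
#' @param seed integer seed controlling all splits.
#' @param stratified sample the test set per class (guarantees every class
#'   in training); `FALSE` gives plain random splits with resampling if a
#'   class is missing from training.
#' @param lda_scope `"fold"` fits the discriminant on the training portion
#'   of each split only (no information leakage); `"global"` fits it once on
#'   the full table before splitting (the classical feed-forward order).
#' @param group_aware if `TRUE`, whole specimens (`group_ids`) are assigned
#'   to test or training, so images of one individual never straddle the
#'   split; off by default.
#' @return an object of class `eval_scheme`.
#' @export
eval_scheme <- function(test_fraction = 0.2, repeats = 10L, seed = 1L,
                        stratified = TRUE, lda_scope = c("fold", "global"),
                        group_aware = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  structure(list(test_fraction = test_fraction, repeats = as.integer(repeats),
                 seed = as.integer(seed), stratified = isTRUE(stratified),
                 lda_scope = match.arg(lda_scope),
                 group_aware = isTRUE(group_aware)),
            class = "eval_scheme")
}

split_indices <- function(labels, test_fraction, stratified,
                          group_ids = NULL) {
  n <- length(labels)
  if (!is.null(group_ids)) {
    # whole groups go to test, sampled within each class until the class's
    # test quota is reached
    test <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      quota <- max(1L, round(length(ix) * test_fraction))
      gs <- sample(unique(group_ids[ix]))
      picked <- integer(0)
      for (g in gs) {
        if (length(picked) >= quota) break
        picked <- c(picked, ix[group_ids[ix] == g])
      }
      picked
    }), use.names = FALSE)
    return(sort(test))
  }
  if (stratified) {
    test <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      k <- max(1L, round(length(ix) * test_fraction))
      sample(ix, k)
    }), use.names = FALSE)
  } else {
    repeat {
      test <- sample.int(n, max(1L, round(n * test_fraction)))
      if (length(unique(labels[-test])) == length(unique(labels))) break
    }
  }
  sort(test)
}

#' Evaluate classifiers under repeated random splits
#'
#' For each repeat the table is split into test and training sets (1:4 by
#' default), reduced with the Fisher discriminant according to the scheme's
#' `lda_scope`, and scored with a k-nearest-neighbour classifier (`k = 9`),
#' multinomial logistic regression and a linear support-vector machine.
#'
#' @param table a [feature_table()] (raw features; reduction is applied
#'   internally) or a `reduced_features` table with `reduce = FALSE`.
#' @param scheme an [eval_scheme()].
#' @param classifiers subset of `c("knn9", "logistic", "linear_svm")`.
#' @param k neighbourhood size of the k-NN classifier.
#' @param reduce apply [lda_reduce()] (default `TRUE`).
#' @return an `accuracy_report`: list with per-classifier `mean`, `sd` and
#'   `per_repeat` accuracies, and a summed `confusion` matrix per classifier.
#' @export
evaluate <- function(table, scheme = eval_scheme(),
                     classifiers = c("knn9", "logistic", "linear_svm"),
                     k = 9L, reduce = TRUE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  labels <- ft_labels(table)
  if (any(base::table(labels) < 2L))
    stop("every class needs at least 2 rows", call. = FALSE)
  lv <- sort(unique(labels))
  acc <- matrix(NA_real_, scheme$repeats, length(classifiers),
                dimnames = list(NULL, classifiers))
  conf <- lapply(classifiers, function(cl)
    matrix(0L, length(lv), length(lv), dimnames = list(truth = lv, pred = lv)))
  names(conf) <- classifiers

  global_red <- if (reduce && scheme$lda_scope == "global") lda_reduce(table) else NULL

  for (r in seq_len(scheme$repeats)) {
    with_seed(derive_seed(scheme$seed, r), {
      gids <- if (scheme$group_aware) attr(table, "group_ids")
      test <- split_indices(labels, scheme$test_fraction, scheme$stratified,
                            group_ids = gids)
      train <- setdiff(seq_len(nrow(table)), test)
      if (reduce) {
        if (scheme$lda_scope == "fold") {
          red <- lda_reduce(ft_subset(table, train))
          tr_x <- unclass(red)
          te_x <- predict(red, unclass(table)[test, , drop = FALSE])
        } else {
          tr_x <- unclass(global_red)[train, , drop = FALSE]
          te_x <- unclass(global_red)[test, , drop = FALSE]
        }
      } else {
        tr_x <- unclass(table)[train, , drop = FALSE]
        te_x <- unclass(table)[test, , drop = FALSE]
      }
      tr_y <- factor(labels[train], levels = lv)
      te_y <- factor(labels[test], levels = lv)
      for (cl in classifiers) {
        pred <- switch(cl,
          knn9 = knn_predict(tr_x, tr_y, te_x, k = k),
          logistic = logistic_predict(logistic_fit(tr_x, tr_y), te_x),
          linear_svm = svm_predict(svm_fit(tr_x, tr_y), te_x))
        pred <- factor(as.character(pred), levels = lv)
        acc[r, cl] <- mean(pred == te_y)
        conf[[cl]] <- conf[[cl]] + unclass(base::table(te_y, pred))
      }
    })
  }
  structure(list(accuracy = acc,
                 mean = colMeans(acc),
                 sd = apply(acc, 2L, sd),
                 confusion = conf,
                 scheme = scheme,
                 n = nrow(table),
                 classes = lv),
            class = "accuracy_report")
}

#' @exportS3Method base::print
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d images, %d classes, %d repeats\n",
              x$n, length(x$classes), nrow(x$accuracy)))
  for (cl in colnames(x$accuracy))
    cat(sprintf("  %-10s mean %.3f (sd %.3f)\n", cl, x$mean[cl], x$sd[cl]))
  invisible(x)
}

# ---- Ward clustering ------------------------------------------------------

#' Ward hierarchical clustering of images
#'
#' Agglomerative clustering with Ward's criterion on Euclidean distances
#' over all rows of a (reduced) feature table.
#'
#' @param table a `reduced_features`/[feature_table()] object or matrix.
#' @param labels optional leaf labels (defaults to `image_ids` or row
#'   numbers, with the class label appended when available).
#' @return a `dendrogram_model`: list with `merge`, `height`, `order`,
#'   `labels` and the underlying `hclust` object.
#' @export
ward_cluster <- function(table, labels = NULL) {
  x <- as.matrix(unclass(table))
  if (nrow(x) < 2L) stop("at least two rows are required", call. = FALSE)
  if (is.null(labels)) {
    ids <- attr(table, "image_ids") %||% seq_len(nrow(x))
    cls <- attr(table, "labels")
    labels <- if (!is.null(cls)) sprintf("%s_%s", cls, ids) else as.character(ids)
  }
  hc <- hclust(dist(x), method = "ward.D2")
  hc$labels <- as.character(labels)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "dendrogram_model")
}

#' @exportS3Method base::print
print.dendrogram_model <- function(x, ...) {
  cat(sprintf("<dendrogram_model> %d leaves, %d merges (Ward)\n",
              length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Ward dendrogram of class centroids
#'
#' Clusters the per-class mean coordinates of a reduced feature table,
#' giving a taxon-level tree.
#'
#' @param table a `reduced_features` object (or any labelled feature table).
#' @return a `dendrogram_model` with one leaf per class.
#' @export
class_dendrogram <- function(table) {
  labs <- ft_labels(table)
  m <- rowsum(as.matrix(unclass(table)), labs) / as.vector(base::table(labs))
  ward_cluster(m, labels = rownames(m))
}

#' Export a dendrogram as Newick
#'
#' Leaf names are the model's labels; branch lengths are merge-height
#' increments (via [ape::as.phylo()]).
#'
#' @param model a `dendrogram_model`.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
export_newick <- function(model, path = NULL) {
  ph <- ape::as.phylo(model$hclust)
  if (is.null(path)) return(ape::write.tree(ph))
  ape::write.tree(ph, file = path)
  invisible(ape::write.tree(ph))
}

#' Classification accuracy across image resolutions
#'
#' Downscales every image to each requested size (through the default
#' stepwise ladder), extracts features with the requested method and
#' evaluates the classifiers, tabulating accuracy per size.
#'
#' @param images list of labelled [micrograph()] objects (square).
#' @param sizes integer vector of target side lengths.
#' @param features `"pores"` or `"sift"`.
#' @param scheme an [eval_scheme()].
#' @param params feature parameters ([pore_params()] or [sift_params()]).
#' @param ... passed to [evaluate()].
#' @return a `resolution_sweep` object: list of `accuracy_report`s (one per
#'   size) plus a `summary` data frame with one row per size.
#' @export
resolution_sweep <- function(images, sizes, features = c("pores", "sift"),
                             scheme = eval_scheme(), params = NULL, ...) {
  features <- match.arg(features)
  reports <- lapply(as.integer(sizes), function(s) {
    resized <- lapply(images, function(im)
      if (nrow(im$pixels) == s) im else downscale_stepwise(im, target = s))
    ftab <- if (features == "pores")
      pore_feature_table(resized, params %||% pore_params())
    else sift_feature_table(resized, params %||% sift_params())
    evaluate(ftab, scheme, ...)
  })
  names(reports) <- as.character(sizes)
  summ <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(size = as.integer(sizes[i]),
               classifier = names(reports[[i]]$mean),
               mean_accuracy = unname(reports[[i]]$mean),
               sd = unname(reports[[i]]$sd), row.names = NULL)
  }))
  structure(list(reports = reports, summary = summ),
            class = "resolution_sweep")
}

#' @exportS3Method base::print
print.resolution_sweep <- function(x, ...) {
  cat("<resolution_sweep>\n")
  print(x$summary)
  invisible(x)
}
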