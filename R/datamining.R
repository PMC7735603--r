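## --- learner families -------------------------------------------------
##
## Five families, seven configurations: decision tree, multinomial-logistic
## ("linear"), regularized discriminant analysis, linear SVM, and
## k-nearest neighbours with k = 1, 3, 5. Binary-only learners (SVM, LDA)
## are wrapped one-vs-one with hinge-loss decoding; the others are
## natively multiclass. Features are z-scored on the training fold for the
## distance-based learners (SVM, kNN).

#' Learner configurations of the classification grid
#'
#' @return character vector of the seven learner tags.
#' @export
learner_configs <- function() c("tree", "linear", "discriminant",
                                "svm", "knn1", "knn3", "knn5")

## one-vs-one wrapper with loss-weighted decoding; `fit_binary` returns a
## function(newx) -> numeric margins (positive = second class).
ovo_predict <- function(train_x, train_y, test_x, fit_binary) {
  lev <- levels(train_y)
  pairs <- utils::combn(lev, 2)
  loss <- matrix(0, nrow(test_x), length(lev), dimnames = list(NULL, lev))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- train_y %in% c(a, b)
    yb <- as.numeric(train_y[sel] == b) * 2 - 1 # a -> -1, b -> +1
    margins <- fit_binary(train_x[sel, , drop = FALSE], yb, test_x)
    ## hinge loss of each hypothesized class
    loss[, a] <- loss[, a] + pmax(0, 1 - (-1) * margins)
    loss[, b] <- loss[, b] + pmax(0, 1 - (+1) * margins)
  }
  factor(lev[apply(loss, 1, which.min)], levels = lev)
}

fit_binary_svm <- function(x, yb, newx) {
  fit <- e1071::svm(x, factor(yb), kernel = "linear", cost = 1, scale = FALSE)
  dv <- attr(stats::predict(fit, newx, decision.values = TRUE), "decision.values")
  ## orient decision values so positive means class +1
  if (colnames(dv)[1] == "-1/1") -dv[, 1] else dv[, 1]
}

## regularized linear discriminant: pooled covariance ridged toward its
## mean diagonal, margin = projection onto S^-1 (mu1 - mu0).
fit_binary_rlda <- function(x, yb, newx) {
  m1 <- colMeans(x[yb > 0, , drop = FALSE])
  m0 <- colMeans(x[yb < 0, , drop = FALSE])
  xc <- rbind(sweep(x[yb > 0, , drop = FALSE], 2, m1),
              sweep(x[yb < 0, , drop = FALSE], 2, m0))
  S <- crossprod(xc) / max(nrow(x) - 2, 1)
  lam <- 1e-3 * mean(diag(S)) + 1e-12
  w <- solve(S + lam * diag(ncol(x)), m1 - m0)
  thr <- sum(w * (m1 + m0)) / 2
  sc <- drop(as.matrix(newx) %*% w) - thr
  sc / max(stats::sd(sc), 1e-12)
}

train_predict <- function(learner, train_x, train_y, test_x) {
  train_y <- droplevels(as.factor(train_y))
  if (learner %in% c("svm", "knn1", "knn3", "knn5")) {
    mu <- colMeans(train_x)
    sg <- apply(train_x, 2, stats::sd); sg[sg == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sg, `/`)
    test_x <- sweep(sweep(test_x, 2, mu), 2, sg, `/`)
  }
  switch(learner,
    tree = {
      df <- data.frame(.y = train_y, train_x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         minbucket = 2))
      stats::predict(fit, data.frame(test_x, check.names = FALSE), type = "class")
    },
    linear = {
      df <- data.frame(.y = train_y, train_x, check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            MaxNWts = 1e6, maxit = 200)
      pr <- stats::predict(fit, data.frame(test_x, check.names = FALSE))
      factor(as.character(pr), levels = levels(train_y))
    },
    discriminant = ovo_predict(train_x, train_y, test_x, fit_binary_rlda),
    svm = ovo_predict(train_x, train_y, test_x, fit_binary_svm),
    knn1 = class::knn(train_x, test_x, train_y, k = 1),
    knn3 = class::knn(train_x, test_x, train_y, k = 3),
    knn5 = class::knn(train_x, test_x, train_y, k = 5),
    stopf("unknown learner: %s", learner))
}

#' Cross-validated accuracy of a single feature set
#'
#' Stratified k-fold cross-validation of one learner configuration;
#' accuracy is 1 minus the mean classification loss.
#'
#' @param features n x p matrix.
#' @param labels class label per row (>= 2 classes, each with >= 2 members).
#' @param learner one of [learner_configs()].
#' @param folds number of CV folds; reduced (with a warning) to the
#'   smallest class size if that is smaller.
#' @param seed integer RNG seed for the fold partition.
#' @return scalar accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(features, labels, learner = "knn1", folds = 10,
                        seed = 1) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  min_cl <- min(table(y))
  if (min_cl < 2) stopf("class '%s' has fewer than 2 members",
                        names(which.min(table(y))))
  if (folds > min_cl) {
    warnf("reducing folds from %d to smallest class size %d", folds, min_cl)
    folds <- min_cl
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  correct <- 0L
  for (k in seq_len(folds)) {
    te <- fold == k
    pred <- train_predict(learner, X[!te, , drop = FALSE], y[!te],
                          X[te, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  correct / length(y)
}

#' Classification-accuracy grid over map combinations and filter sizes
#'
#' For every (combination, filter size) cell, features are assembled with
#' [assemble_features()] and each learner configuration is scored by
#' stratified 10-fold cross-validation. Cells that fail numerically are
#' recorded as `NA`, not zero.
#'
#' @param mapsets list of `map_set` objects with `group` labels.
#' @param combos combination tags (default all seven).
#' @param f_range integer vector of filter sizes (the study grid is 1:50).
#' @param learners learner configurations (default all seven).
#' @param folds CV folds (default 10).
#' @param seed integer RNG seed (fold partitions are reproducible).
#' @return `ml_grid`: data frame with columns `combo`, `f`, `learner`,
#'   `accuracy`, plus attributes `folds` and `seed`.
#' @export
cv_accuracy_grid <- function(mapsets, combos = names(map_combos()),
                             f_range = 1:50, learners = learner_configs(),
                             folds = 10, seed = 1) {
  groups <- vapply(mapsets, function(m) m$group %||% NA_character_, "")
  if (anyNA(groups)) stopf("all specimens need group labels")
  rows <- list()
  for (combo in combos) {
    for (f in f_range) {
      feats <- tryCatch(assemble_features(mapsets, combo, f),
                        error = function(e) NULL)
      for (lrn in learners) {
        acc <- if (is.null(feats)) NA_real_ else tryCatch(
          cv_accuracy(feats, groups, lrn, folds = folds, seed = seed),
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(combo = combo, f = f, learner = lrn, accuracy = acc)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("ml_grid", "data.frame")
  out
}

#' Most parsimonious model among near-best grid cells
#'
#' Among cells whose accuracy is within `tolerance` of the grid maximum,
#' returns the one with (i) the smallest filter size, then (ii) the fewest
#' map variables, then (iii) the earliest learner in [learner_configs()]
#' order.
#'
#' @param grid an `ml_grid` from [cv_accuracy_grid()].
#' @param tolerance accuracy slack below the maximum (default 0).
#' @return one-row data frame (`combo`, `f`, `learner`, `accuracy`).
#' @export
select_parsimonious_model <- function(grid, tolerance = 0) {
  g <- grid[!is.na(grid$accuracy), , drop = FALSE]
  if (nrow(g) == 0) stopf("empty accuracy grid")
  best <- max(g$accuracy)
  cand <- g[g$accuracy >= best - tolerance, , drop = FALSE]
  nvars <- lengths(map_combos())[cand$combo]
  lorder <- match(cand$learner, learner_configs())
  ord <- order(cand$f, nvars, lorder)
  cand[ord[1], , drop = FALSE]
}

#' Phylogenetic-signal grid over map combinations and filter sizes
#'
#' For every (combination, filter size) cell, assembles aligned features,
#' averages them per tip label when a tip has several specimens, and
#' computes the multivariate K statistic against the tree.
#'
#' @param mapsets list of `map_set` objects whose `group` labels are tree
#'   tip labels (typically one species-mean map set per tip).
#' @param tree `ape::phylo` over the same labels.
#' @param combos combination tags (default all seven).
#' @param f_range filter sizes (the study grid is 1:100).
#' @return `k_grid`: data frame with columns `combo`, `f`, `k_value`, plus
#'   the argmax as attribute `best`.
#' @export
phylo_signal_grid <- function(mapsets, tree, combos = names(map_combos()),
                              f_range = 1:100) {
  groups <- vapply(mapsets, function(m) m$group %||% NA_character_, "")
  if (anyNA(groups)) stopf("all specimens need tip labels as groups")
  if (!setequal(unique(groups), tree$tip.label))
    stopf("specimen groups and tree tips differ: %s",
          paste(c(setdiff(unique(groups), tree$tip.label),
                  setdiff(tree$tip.label, unique(groups))), collapse = ", "))
  C <- phylo_covariance(tree)
  rows <- list()
  for (combo in combos) {
    for (f in f_range) {
      kv <- tryCatch({
        feats <- assemble_features(mapsets, combo, f)
        tipmeans <- rowsum(unclass(feats), groups) /
          as.vector(table(groups)[sort(unique(groups))])
        k_mult(tipmeans, C)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(combo = combo, f = f, k_value = kv)
    }
  }
  out <- do.call(rbind, rows)
  ok <- which(!is.na(out$k_value))
  attr(out, "best") <- out[ok[which.max(out$k_value[ok])], , drop = FALSE]
  class(out) <- c("k_grid", "data.frame")
  out
}
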