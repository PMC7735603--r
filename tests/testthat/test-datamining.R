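## Gaussian-blob feature fixture: 3 well-separated classes.
blob_features <- function(n_per = 8, p = 10, sep = 6, sd = 1, seed = 21) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * p), 3, p) * sep
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * p, 0, sd), n_per, p), 2, centers[k, ], `+`)))
  list(X = X, y = factor(rep(paste0("cl", 1:3), each = n_per)))
}

test_that("all learner families separate well-separated classes", {
  bf <- blob_features()
  for (lrn in learner_configs()) {
    acc <- cv_accuracy(bf$X, bf$y, lrn, folds = 4, seed = 1)
    expect_gte(acc, 0.9)
  }
})

test_that("permuted labels and duplicated classes score at chance", {
  bf <- blob_features()
  set.seed(99)
  acc_perm <- cv_accuracy(bf$X, sample(bf$y), "knn1", folds = 4, seed = 1)
  expect_lt(abs(acc_perm - 1 / 3), 0.15 + 1e-9)

  ## two classes drawn from one distribution: indistinguishable, near 0.5
  set.seed(7)
  Xd <- matrix(rnorm(40 * 5), 40, 5)
  yd <- factor(rep(c("a", "b"), 20))
  acc_dup <- cv_accuracy(Xd, yd, "knn3", folds = 4, seed = 2)
  expect_lt(abs(acc_dup - 0.5), 0.2)
})

test_that("cross-validation is seeded, stratified and degrades gracefully", {
  bf <- blob_features()
  a1 <- cv_accuracy(bf$X, bf$y, "svm", folds = 4, seed = 5)
  a2 <- cv_accuracy(bf$X, bf$y, "svm", folds = 4, seed = 5)
  expect_identical(a1, a2)

  expect_error(cv_accuracy(bf$X, factor(rep("one", 24)), "knn1"), "2 classes")
  y_small <- bf$y; y_small[1:7] <- "cl2"
  expect_error(cv_accuracy(bf$X, factor(c("a", rep("b", 23))), "knn1"),
               "fewer than 2")
  expect_warning(cv_accuracy(bf$X[1:9, ], factor(rep(c("a", "b", "c"), 3)),
                             "knn1", folds = 10), "reducing folds")
})

test_that("accuracy is invariant to adding a constant to all features", {
  bf <- blob_features(n_per = 6, p = 6)
  for (lrn in c("knn1", "svm", "discriminant", "tree")) {
    a0 <- cv_accuracy(bf$X, bf$y, lrn, folds = 3, seed = 3)
    a1 <- cv_accuracy(bf$X + 50, bf$y, lrn, folds = 3, seed = 3)
    expect_equal(a0, a1, info = lrn)
  }
})

test_that("the accuracy grid runs on map sets and records failures as NA", {
  mapsets <- strain_mapsets(n = 4, grid = 32)
  grid <- cv_accuracy_grid(mapsets, combos = c("Nxyz", "hr"),
                           f_range = c(2, 6), learners = c("knn1", "svm"),
                           folds = 4, seed = 1)
  expect_s3_class(grid, "ml_grid")
  expect_equal(nrow(grid), 2 * 2 * 2)
  expect_true(all(is.na(grid$accuracy) | (grid$accuracy >= 0 & grid$accuracy <= 1)))
  expect_gte(max(grid$accuracy, na.rm = TRUE), 0.9)

  ## reproducibility of a grid cell
  grid2 <- cv_accuracy_grid(mapsets, combos = "Nxyz", f_range = 6,
                            learners = "knn1", folds = 4, seed = 1)
  expect_identical(grid$accuracy[grid$combo == "Nxyz" & grid$f == 6 &
                                   grid$learner == "knn1"],
                   grid2$accuracy)
})

test_that("parsimonious model selection applies the tie-break order", {
  grid <- data.frame(
    combo = c("Nxyz", "chrNxyz", "c", "hr"),
    f = c(6, 20, 6, 3),
    learner = c("svm", "knn1", "tree", "svm"),
    accuracy = c(0.79, 0.79, 0.70, 0.78))
  class(grid) <- c("ml_grid", "data.frame")
  sel <- select_parsimonious_model(grid, tolerance = 0)
  expect_equal(sel$combo, "Nxyz"); expect_equal(sel$f, 6)

  ## smaller f wins within tolerance even at lower accuracy
  sel2 <- select_parsimonious_model(grid, tolerance = 0.01)
  expect_equal(sel2$combo, "hr")

  ## fewest variables, then learner order, break exact ties at equal f
  grid3 <- data.frame(combo = c("chr", "c"), f = c(3, 3),
                      learner = c("tree", "knn5"), accuracy = c(0.9, 0.9))
  expect_equal(select_parsimonious_model(grid3)$combo, "c")
  grid4 <- data.frame(combo = c("c", "c"), f = c(3, 3),
                      learner = c("knn5", "tree"), accuracy = c(0.9, 0.9))
  expect_equal(select_parsimonious_model(grid4)$learner, "tree")

  expect_equal(nrow(select_parsimonious_model(grid[1, ])), 1)
  expect_error(select_parsimonious_model(grid[0, ]), "empty")
})

test_that("the phylogenetic-signal grid is exactly one on a star tree", {
  mapsets <- strain_mapsets(n = 4, grid = 32)
  ## one tip per specimen group plus one extra tip level split
  groups <- vapply(mapsets, `[[`, "", "group")
  star <- ape::stree(3, type = "star")
  star$tip.label <- unique(groups)
  star$edge.length <- rep(1, nrow(star$edge))
  kg <- phylo_signal_grid(mapsets, star, combos = c("Nxyz", "hr"),
                          f_range = c(2, 4))
  expect_true(all(abs(kg$k_value - 1) < 1e-8))

  bad <- star; bad$tip.label <- c("x", "y", "z")
  expect_error(phylo_signal_grid(mapsets, bad, combos = "hr", f_range = 2),
               "differ")
})

test_that("signal-grid K values are invariant to feature-order permutation", {
  set.seed(17)
  tr <- ape::rcoal(8)
  X <- simulate_bm_traits(tr, 12, seed = 2)
  k0 <- k_mult(X, tr)
  k1 <- k_mult(X[, sample(12)], tr)
  expect_equal(k0, k1, tolerance = 1e-12)
})
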