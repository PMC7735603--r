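test_that("the BM covariance holds shared path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_covariance(tr2)), diag(2))
  ## ultrametric: constant diagonal
  tru <- ape::rcoal(12)
  expect_lt(diff(range(diag(phylo_covariance(tru)))), 1e-8)
})

test_that("multivariate K is one on a star tree and matches the univariate oracle", {
  star <- ape::stree(31, type = "star")
  star$edge.length <- rep(1.7, nrow(star$edge))
  set.seed(9)
  for (i in 1:5) {
    X <- matrix(rnorm(31 * 6), 31, 6)
    rownames(X) <- star$tip.label
    expect_lt(abs(k_mult(X, star) - 1), 1e-8)
  }

  skip_if_not_installed("picante")
  set.seed(13)
  for (i in 1:3) {
    tr <- ape::rtree(8)
    x <- simulate_bm_traits(tr, 1, seed = i)
    expect_equal(k_mult(x, tr),
                 as.numeric(picante::Kcalc(x[tr$tip.label, 1], tr)),
                 tolerance = 1e-10)
  }
})

test_that("the K permutation test detects signal and validates inputs", {
  set.seed(5)
  tr <- ape::rcoal(20)
  X <- simulate_bm_traits(tr, 20, seed = 8)
  kt <- k_permutation_test(X, tr, n_perm = 199, seed = 3)
  expect_lte(kt$p_value, 0.05)
  expect_gt(kt$K, 0)
  expect_error(k_permutation_test(X, tr, n_perm = 0), "n_perm")
})

test_that("between-group PCA has the documented geometry", {
  ## collinear group means: all variance on PC1
  means <- rbind(c(0, 0, 0, 0, 0), c(1, 2, 0, 0, 0), c(2, 4, 0, 0, 0))
  rownames(means) <- c("g1", "g2", "g3")
  sp <- between_group_pca(means, rownames(means))
  expect_equal(sp$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(sum(sp$variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))

  expect_error(between_group_pca(means[c(1, 1), ], c("a", "b")), "zero")
  expect_error(between_group_pca(means[1, , drop = FALSE], "a"), "2 groups")

  ## full-rank scores reproduce inter-mean distances
  set.seed(3)
  M6 <- matrix(rnorm(6 * 20), 6, 20)
  rownames(M6) <- paste0("g", 1:6)
  sp6 <- between_group_pca(M6, rownames(M6))
  expect_equal(as.matrix(dist(sp6$scores)), as.matrix(dist(M6)),
               tolerance = 1e-9, ignore_attr = TRUE)

  ## projection: the group means project onto their own scores
  sp7 <- between_group_pca(M6, rownames(M6), project = M6)
  expect_equal(unname(sp7$projected), unname(sp7$scores), tolerance = 1e-9)
})

test_that("ancestral states solve weighted squared-change parsimony", {
  tr2 <- ape::read.tree(text = "(A:2,B:1);")
  z <- ancestral_states(tr2, matrix(c(4, 1), 2, 1,
                                    dimnames = list(c("A", "B"))))
  expect_equal(unname(z[1, 1]), (4 / 2 + 1 / 1) / (1 / 2 + 1 / 1))
  tr_eq <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(ancestral_states(tr_eq, matrix(c(4, 1), 2, 1,
                                       dimnames = list(c("A", "B"))))[1, 1]),
               2.5)

  ## all tips equal: every ancestor equals that value
  tr5 <- ape::rtree(5)
  zc <- ancestral_states(tr5, matrix(3.3, 5, 2,
                                     dimnames = list(tr5$tip.label)))
  expect_lt(max(abs(zc - 3.3)), 1e-10)

  ## direct numeric minimization oracle
  set.seed(14)
  tr5b <- ape::rtree(5)
  x <- rnorm(5); names(x) <- tr5b$tip.label
  obj <- function(z) {
    states <- c(x[tr5b$tip.label], z)
    sum((states[tr5b$edge[, 1]] - states[tr5b$edge[, 2]])^2 / tr5b$edge.length)
  }
  opt <- optim(rep(0, tr5b$Nnode), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  za <- ancestral_states(tr5b, matrix(x, 5, 1, dimnames = list(names(x))))
  expect_equal(unname(za[, 1]), opt$par, tolerance = 1e-6)

  skip_if_not_installed("phytools")
  fa <- phytools::fastAnc(tr5b, x)
  expect_equal(unname(za[names(fa), 1]), unname(c(fa)), tolerance = 1e-8)
})

test_that("PGLS with an identity tree reduces to permutation MANOVA", {
  set.seed(22)
  n <- 12
  Ct <- diag(n); rownames(Ct) <- colnames(Ct) <- paste0("t", 1:n)
  Y <- matrix(rnorm(n * 4), n, 4, dimnames = list(rownames(Ct)))
  g <- factor(rep(c("a", "b", "c"), 4)); names(g) <- rownames(Ct)
  pg <- pgls_categorical(Y, Ct, g, n_perm = 99, seed = 1)

  ## direct (non-phylogenetic) trace-based R^2
  fitf <- lm(Y ~ g); fitr <- lm(Y ~ 1)
  ss_res <- sum(resid(fitf)^2); ss_tot <- sum(resid(fitr)^2)
  expect_equal(pg$R2, (ss_tot - ss_res) / ss_tot, tolerance = 1e-10)

  ## strong group shifts: significant
  Y2 <- Y; Y2[g == "a", ] <- Y2[g == "a", ] + 8
  pg2 <- pgls_categorical(Y2, Ct, g, n_perm = 199, seed = 2)
  expect_lte(pg2$p_value, 0.01)

  expect_error(pgls_categorical(Y, Ct, factor(rep("x", n)), n_perm = 9),
               "2 categories")
})

test_that("pseudo-genetic coding reproduces the dosage arithmetic", {
  gt <- data.frame(strain = c("mutA", "mutA", "gainB", "WT"),
                   gene = c("g1", "g2", "g2", "g1"),
                   dosage = c("loss", "hetero", "gain", "normal"))
  pd <- pseudo_genetic_distance(gt)
  expect_equal(unname(pd$from_wt["mutA"]), 1.5)
  expect_equal(unname(pd$from_wt["WT"]), 0)
  expect_equal(unname(pd$from_wt["gainB"]), 1)
  ## pairwise L1: mutA (0, 0.5) vs gainB (1, 2) -> 1 + 1.5
  expect_equal(pd$pairwise["mutA", "gainB"], 2.5)
  gt$dosage[1] <- "duplicated"
  expect_error(pseudo_genetic_distance(gt), "unknown dosage")
})

test_that("the Mantel wrapper is affine-invariant and validates matrices", {
  set.seed(30)
  D1 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  expect_equal(mantel_test(D1, D1, n_perm = 99)$r, 1, tolerance = 1e-12)
  D2 <- 2 * D1 + 3; diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99)$r, 1, tolerance = 1e-12)
  expect_error(mantel_test(D1, D1[1:5, 1:5]), "size")
  expect_error(mantel_test(D1, matrix(0, 12, 12)), "constant")
  asym <- D1; asym[1, 2] <- 99
  expect_error(mantel_test(D1, asym), "symmetric")
  ## reproducible permutation p under a fixed seed
  D3 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  p1 <- mantel_test(D1, D3, n_perm = 199, seed = 4)$p_value
  p2 <- mantel_test(D1, D3, n_perm = 199, seed = 4)$p_value
  expect_identical(p1, p2)
})

test_that("phenetic distances respect rotation invariance and hand arithmetic", {
  set.seed(33)
  M <- matrix(rnorm(5 * 7), 5, 7); rownames(M) <- paste0("g", 1:5)
  sp <- between_group_pca(M, rownames(M))
  Dall <- phenetic_distance_matrix(sp, axes = ncol(sp$scores))
  expect_equal(Dall, as.matrix(dist(M)), tolerance = 1e-9, ignore_attr = TRUE)

  sc <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 4))
  D2 <- phenetic_distance_matrix(sc, axes = 2)
  expect_equal(D2["a", "b"], 5, tolerance = 1e-12)
  expect_equal(D2["b", "c"], 3, tolerance = 1e-12)
  expect_error(phenetic_distance_matrix(sc, axes = 0), "axes")
  expect_error(phenetic_distance_matrix(sc, axes = 9), "available")
})

test_that("hull coverage flags match a brute-force half-plane oracle", {
  set.seed(40)
  A <- matrix(rnorm(40), 20, 2); rownames(A) <- paste0("a", 1:20)
  B <- matrix(rnorm(40, 0, 1.5), 20, 2); rownames(B) <- paste0("b", 1:20)
  S <- rbind(A, B)
  hc <- hull_coverage(S, rownames(A), rownames(B))

  ## oracle: point is inside iff inside every half-plane of the hull
  inside_bf <- function(q, hull) {
    n <- nrow(hull)
    sgn <- vapply(seq_len(n), function(i) {
      a <- hull[i, ]; b <- hull[i %% n + 1, ]
      sign((b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1]))
    }, 0)
    all(sgn >= 0) || all(sgn <= 0)
  }
  hull_a <- hc$hull_A[-nrow(hc$hull_A), ]
  for (i in seq_len(nrow(B))) {
    expect_equal(hc$B_in_A[i] != "outside", inside_bf(B[i, ], hull_a),
                 info = paste("point", i))
  }

  ## subset points are inside or on; far-translated points are outside
  Bsub <- A[1:5, ]; rownames(Bsub) <- paste0("s", 1:5)
  hc2 <- hull_coverage(rbind(A, Bsub), rownames(A), rownames(Bsub))
  expect_true(all(hc2$B_in_A %in% c("inside", "on")))
  Bfar <- A[1:5, ] + 100; rownames(Bfar) <- paste0("f", 1:5)
  hc3 <- hull_coverage(rbind(A, Bfar), rownames(A), rownames(Bfar))
  expect_true(all(hc3$B_in_A == "outside"))
  expect_error(hull_coverage(rbind(A, Bfar[1:2, ]), rownames(A),
                             rownames(Bfar)[1:2]), "at least 3")
})
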