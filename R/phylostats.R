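#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds tip depths.
#'
#' @param tree an `ape::phylo` with positive branch lengths.
#' @return N x N matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stopf("tip labels are not unique")
  ape::vcv(tree)
}

#' Multivariate phylogenetic signal (K statistic)
#'
#' Generalization of Blomberg's K to multivariate traits: with phylogenetic
#' mean `a = (1'C^-1 1)^-1 (1'C^-1 X)`, observed-to-expected ratio of the
#' trace-based mean squared error under the star versus the BM-implied
#' metric,
#' `K = (D0/D) / ((tr C - N / (1'C^-1 1)) / (N - 1))`
#' with `D0 = tr[(X-1a)'(X-1a)]` and `D = tr[(X-1a)'C^-1(X-1a)]`.
#' K = 1 is the Brownian-motion expectation; K < 1 means relatives resemble
#' each other less than BM predicts.
#'
#' @param X N x p trait matrix, rows ordered as (or named by) the rows of C.
#' @param C phylogenetic covariance from [phylo_covariance()] (or a tree).
#' @return scalar K.
#' @export
k_mult <- function(X, C) {
  if (inherits(C, "phylo")) C <- phylo_covariance(C)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 3) stopf("need at least 3 tips")
  if (nrow(C) != N) stopf("X and C dimensions disagree")
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    if (!setequal(rownames(X), rownames(C))) stopf("tip labels of X and C differ")
    X <- X[rownames(C), , drop = FALSE]
  }
  Ci <- tryCatch(solve(C), error = function(e) stopf("singular phylogenetic covariance"))
  one <- matrix(1, N, 1)
  denom_a <- drop(t(one) %*% Ci %*% one)
  a <- (t(one) %*% Ci %*% X) / denom_a
  R <- X - one %*% a
  D0 <- sum(R * R)
  D <- sum(R * (Ci %*% R))
  expected <- (sum(diag(C)) - N / denom_a) / (N - 1)
  (D0 / D) / expected
}

#' Permutation test for the multivariate K statistic
#'
#' Permutes tip labels (rows of X against the tree) `n_perm` times;
#' `p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1)`.
#'
#' @param X N x p trait matrix.
#' @param tree `ape::phylo` (or a covariance matrix).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `K`, `p_value`, `n_perm`.
#' @export
k_permutation_test <- function(X, tree, n_perm = 999, seed = 1) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !is.null(rownames(C)))
    X <- X[rownames(C), , drop = FALSE]
  k_obs <- k_mult(unname(X), unname(C))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k_perm <- vapply(seq_len(n_perm), function(i) {
    k_mult(unname(X[sample.int(nrow(X)), , drop = FALSE]), unname(C))
  }, 0)
  list(K = k_obs, p_value = (1 + sum(k_perm >= k_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Between-group principal component analysis
#'
#' Eigendecomposition of the covariance matrix of group mean feature
#' vectors; individual specimens (and reconstructed ancestors) can be
#' projected onto the group-mean axes.
#'
#' @param features n x p matrix of feature vectors.
#' @param groups group label per row; group means are computed internally.
#'   If `features` already holds one row per group, pass distinct labels.
#' @param project optional matrix of extra rows to project (e.g. individual
#'   specimens or ancestral states), p columns.
#' @return a `morphospace`: list with `scores` (group means on the PCs),
#'   `projected`, `eigenvectors`, `eigenvalues`, `variance_fraction`,
#'   `center`, `group_means`.
#' @export
between_group_pca <- function(features, groups = rownames(features),
                              project = NULL) {
  X <- as.matrix(features)
  if (is.null(groups)) stopf("group labels required")
  groups <- as.character(groups)
  means <- rowsum(X, groups) / as.vector(table(groups)[sort(unique(groups))])
  g <- nrow(means)
  if (g < 2) stopf("between-group PCA needs at least 2 groups")
  ctr <- colMeans(means)
  Mc <- sweep(means, 2, ctr)
  total_var <- sum(Mc^2) / (g - 1)
  if (total_var == 0) stopf("group means are identical: zero between-group variance")
  ## eigendecomposition via SVD of the centered means (rank <= g-1)
  sv <- svd(Mc)
  r <- min(g - 1, ncol(X))
  eigvec <- sv$v[, seq_len(r), drop = FALSE]
  eigval <- (sv$d[seq_len(r)]^2) / (g - 1)
  scores <- Mc %*% eigvec
  colnames(scores) <- paste0("PC", seq_len(r))
  rownames(scores) <- rownames(means)
  proj <- NULL
  if (!is.null(project)) {
    proj <- sweep(as.matrix(project), 2, ctr) %*% eigvec
    colnames(proj) <- colnames(scores)
  }
  structure(list(scores = scores, projected = proj, eigenvectors = eigvec,
                 eigenvalues = eigval,
                 variance_fraction = eigval / sum(eigval),
                 center = ctr, group_means = means),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[seq_len(min(3, length(x$variance_fraction)))], 1)
  cat(sprintf("morphospace: %d groups, %d axes; variance %% = %s\n",
              nrow(x$scores), length(x$eigenvalues),
              paste(vf, collapse = "/")))
  invisible(x)
}

#' Squared-change-parsimony ancestral states
#'
#' Internal-node values minimizing the branch-length-weighted sum of
#' squared changes along the tree, per trait — equivalent to maximum
#' likelihood under Brownian motion. Solved as one sparse linear system in
#' the internal nodes.
#'
#' @param tree `ape::phylo` with positive branch lengths.
#' @param tip_scores N x p matrix (rows named by, or ordered as, the tips).
#' @return (N_internal) x p matrix of reconstructed states, rows named by
#'   internal node number (root first, `ape` numbering).
#' @export
ancestral_states <- function(tree, tip_scores) {
  X <- as.matrix(tip_scores)
  n_tip <- length(tree$tip.label)
  if (nrow(X) != n_tip) stopf("tip_scores rows must match the tree tips")
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tree$tip.label)) stopf("tip labels differ from the tree")
    X <- X[tree$tip.label, , drop = FALSE]
  }
  if (any(tree$edge.length <= 0)) stopf("ancestral states need positive branch lengths")
  n_node <- tree$Nnode
  n_all <- n_tip + n_node
  w <- 1 / tree$edge.length
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  ## graph Laplacian over all nodes
  Lap <- matrix(0, n_all, n_all)
  for (k in seq_along(w)) {
    i <- e1[k]; j <- e2[k]
    Lap[i, i] <- Lap[i, i] + w[k]; Lap[j, j] <- Lap[j, j] + w[k]
    Lap[i, j] <- Lap[i, j] - w[k]; Lap[j, i] <- Lap[j, i] - w[k]
  }
  int <- (n_tip + 1):n_all
  tips <- 1:n_tip
  Z <- solve(Lap[int, int, drop = FALSE],
             -Lap[int, tips, drop = FALSE] %*% X)
  rownames(Z) <- as.character(int)
  colnames(Z) <- colnames(X)
  Z
}

#' Phylogenetic generalized least squares with a categorical predictor
#'
#' Multivariate PGLS of features on a factor (e.g. diet category) under the
#' Brownian covariance: responses and the dummy-coded design are whitened
#' by `P` with `P'P = C^-1`, sums of squares are taken as traces of
#' residual cross-products, and significance comes from residual
#' randomization under the reduced (intercept-only) model (RRPP).
#'
#' @param Y N x p feature matrix, rows named by taxa.
#' @param tree `ape::phylo` (or covariance matrix) over the same taxa.
#' @param category factor of group labels per taxon (>= 2 levels).
#' @param n_perm RRPP permutations.
#' @param seed integer RNG seed.
#' @return list with `R2`, `F`, `p_value`, `df`, `n_perm`.
#' @export
pgls_categorical <- function(Y, tree, category, n_perm = 999, seed = 1) {
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else as.matrix(tree)
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C))) stopf("taxa of Y and tree differ")
    if (!is.null(names(category))) category <- category[rownames(C)]
    else category <- category[match(rownames(C), rownames(Y))]
    Y <- Y[rownames(C), , drop = FALSE]
  }
  category <- droplevels(as.factor(category))
  if (nlevels(category) < 2) stopf("need at least 2 categories")
  if (anyNA(category)) stopf("category labels missing for some taxa")
  R <- tryCatch(chol(C), error = function(e) stopf("singular phylogenetic covariance"))
  P <- t(solve(R)) # P'P = C^-1
  Yt <- P %*% Y
  Xf <- P %*% stats::model.matrix(~category)
  Xr <- P %*% matrix(1, N, 1)

  rss <- function(X, Yv) {
    Q <- qr(X)
    sum(stats::resid(stats::lm.fit(X, Yv))^2)
  }
  fit_res <- function(X, Yv) Yv - X %*% qr.coef(qr(X), Yv)
  Rf <- fit_res(Xf, Yt); Rr <- fit_res(Xr, Yt)
  ss_res <- sum(Rf^2); ss_tot <- sum(Rr^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- nlevels(category) - 1
  df_res <- N - nlevels(category)
  Fobs <- (ss_mod / df_mod) / (ss_res / df_res)
  R2 <- ss_mod / ss_tot

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit_r <- Xr %*% qr.coef(qr(Xr), Yt)
  Fperm <- vapply(seq_len(n_perm), function(i) {
    Ystar <- fit_r + Rr[sample.int(N), , drop = FALSE]
    Rfs <- fit_res(Xf, Ystar); Rrs <- fit_res(Xr, Ystar)
    ssm <- sum(Rrs^2) - sum(Rfs^2)
    (ssm / df_mod) / (sum(Rfs^2) / df_res)
  }, 0)
  list(R2 = R2, F = Fobs,
       p_value = (1 + sum(Fperm >= Fobs)) / (n_perm + 1),
       df = c(model = df_mod, residual = df_res), n_perm = n_perm)
}

#' Pseudo-genetic dosage distances
#'
#' Each gene's expression class is coded loss = 0, hetero = 0.5,
#' normal = 1, gain = 2. A strain's distance from wild type is the sum over
#' genes of absolute deviations from the normal code 1 (the sum of its
#' individual mutations); pairwise strain distance is the L1 distance on
#' the code vectors. Genes absent from a strain's record count as normal.
#'
#' @param genotypes data frame with columns `strain`, `gene`, `dosage`
#'   (long format), or a strain x gene matrix/data frame of dosage classes.
#' @return list with `codes` (strain x gene numeric matrix), `from_wt`
#'   (named vector) and `pairwise` (strain x strain matrix).
#' @export
pseudo_genetic_distance <- function(genotypes) {
  code_table <- c(loss = 0, hetero = 0.5, normal = 1, gain = 2)
  if (is.data.frame(genotypes) && all(c("strain", "gene", "dosage") %in% names(genotypes))) {
    strains <- unique(as.character(genotypes$strain))
    genes <- unique(as.character(genotypes$gene))
    codes <- matrix(1, length(strains), length(genes),
                    dimnames = list(strains, genes))
    for (i in seq_len(nrow(genotypes))) {
      d <- as.character(genotypes$dosage[i])
      if (!d %in% names(code_table)) stopf("unknown dosage class: %s", d)
      codes[as.character(genotypes$strain[i]), as.character(genotypes$gene[i])] <-
        code_table[[d]]
    }
  } else {
    m <- as.matrix(genotypes)
    bad <- setdiff(unique(as.vector(m)), names(code_table))
    if (length(bad)) stopf("unknown dosage class: %s", bad[1])
    codes <- matrix(code_table[as.vector(m)], nrow(m), ncol(m),
                    dimnames = dimnames(m))
  }
  from_wt <- rowSums(abs(codes - 1))
  pairwise <- as.matrix(stats::dist(codes, method = "manhattan"))
  list(codes = codes, from_wt = from_wt, pairwise = pairwise)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements with significance by
#' simultaneous row/column permutation of the second matrix
#' (via `vegan::mantel`).
#'
#' @param D1,D2 symmetric distance matrices with zero diagonals.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return list with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stopf("distance matrices differ in size")
  check_dist <- function(D, nm) {
    if (max(abs(D - t(D))) > 1e-8) stopf("%s is not symmetric", nm)
    if (max(abs(diag(D))) > 1e-8) stopf("%s has a nonzero diagonal", nm)
    if (stats::sd(D[lower.tri(D)]) == 0) stopf("%s is constant off-diagonal", nm)
  }
  check_dist(D1, "D1"); check_dist(D2, "D2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                      method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p_value = mt$signif, n_perm = n_perm)
}

#' Pearson correlation of wild-type disparities
#'
#' Correlates per-strain pseudo-genetic distance from wild type with
#' phenetic (morphospace) distance from wild type across strains, and
#' reports the squared correlation of the linear fit.
#'
#' @param genetic named numeric vector of distances from WT.
#' @param phenetic named numeric vector of distances from WT (same strains).
#' @return list with `r`, `r_squared`, `n`.
#' @export
disparity_correlation <- function(genetic, phenetic) {
  if (!is.null(names(genetic)) && !is.null(names(phenetic))) {
    common <- intersect(names(genetic), names(phenetic))
    if (length(common) < 3) stopf("need at least 3 shared strains")
    genetic <- genetic[common]; phenetic <- phenetic[common]
  }
  r <- stats::cor(genetic, phenetic)
  list(r = r, r_squared = r^2, n = length(genetic))
}

#' Phenetic distances in morphospace
#'
#' Pairwise Euclidean distances between group means on the first `axes`
#' principal component axes.
#'
#' @param scores a `morphospace` (or a score matrix).
#' @param axes number of leading axes (default 2).
#' @return symmetric distance matrix.
#' @export
phenetic_distance_matrix <- function(scores, axes = 2) {
  S <- if (inherits(scores, "morphospace")) scores$scores else as.matrix(scores)
  if (axes < 1) stopf("axes must be >= 1")
  if (axes > ncol(S)) stopf("only %d axes available", ncol(S))
  as.matrix(stats::dist(S[, seq_len(axes), drop = FALSE]))
}

#' Convex-hull coverage between two point sets in morphospace
#'
#' Builds the 2D convex hulls of two labelled sets on the first two PC
#' axes and classifies every point of each set as inside, on, or outside
#' the other set's hull.
#'
#' @param scores a `morphospace` or an n x >=2 score matrix with row names.
#' @param set_A,set_B row labels of the two sets (>= 3 points each).
#' @return list with `A_in_B`, `B_in_A` (factors inside/on/outside, named),
#'   and `hull_A`, `hull_B` (hull vertex coordinates, closed rings).
#' @export
hull_coverage <- function(scores, set_A, set_B) {
  S <- if (inherits(scores, "morphospace")) {
    rbind(scores$scores, scores$projected)
  } else as.matrix(scores)
  S <- S[, 1:2, drop = FALSE]
  pa <- S[set_A, , drop = FALSE]; pb <- S[set_B, , drop = FALSE]
  if (nrow(pa) < 3 || nrow(pb) < 3) stopf("each set needs at least 3 points")
  hull_of <- function(p) p[grDevices::chull(p), , drop = FALSE]
  ha <- hull_of(pa); hb <- hull_of(pb)
  classify <- function(pts, hull) {
    res <- apply(pts, 1, function(q) point_in_hull(q, hull))
    factor(res, levels = c("inside", "on", "outside"))
  }
  list(A_in_B = stats::setNames(classify(pa, hb), rownames(pa)),
       B_in_A = stats::setNames(classify(pb, ha), rownames(pb)),
       hull_A = rbind(ha, ha[1, ]), hull_B = rbind(hb, hb[1, ]))
}

## Orientation-test point-in-convex-polygon classification. `hull` is in
## counterclockwise order (chull returns clockwise; handle both).
point_in_hull <- function(q, hull) {
  n <- nrow(hull)
  scale <- max(abs(hull), 1)
  tol <- 1e-9 * scale^2
  cr <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[i %% n + 1, ]
    (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
  }, 0)
  if (any(abs(cr) <= tol)) {
    ## on a supporting line: on the hull if not strictly outside elsewhere
    rest <- cr[abs(cr) > tol]
    if (length(rest) == 0 || all(rest > 0) || all(rest < 0)) return("on")
    return("outside")
  }
  if (all(cr > 0) || all(cr < 0)) "inside" else "outside"
}
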