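#' Parametric tooth-crown specification
#'
#' Describes a synthetic crown as a superellipse cervical outline carrying a
#' low dome plus Gaussian cusp bumps. Defaults emulate a generalized murine
#' lower first molar: two longitudinal rows of three cusps on an elongated
#' outline, dimensions in millimetres.
#'
#' @param outline_a,outline_b semi-axes of the superellipse outline (mm).
#' @param outline_exp superellipse exponent (2 = ellipse; larger = boxier).
#' @param cusps matrix with columns `x`, `y`, `height`, `width` (one row per
#'   cusp); positions must fall inside the outline.
#' @param base_height height of the basal dome at the crown centre (mm).
#' @param mesh_resolution approximate triangle count of the generated mesh.
#' @return object of class `tooth_spec`.
#' @export
tooth_spec <- function(outline_a = 1.5, outline_b = 1.0, outline_exp = 2.5,
                       cusps = default_cusps(), base_height = 0.3,
                       mesh_resolution = 4000) {
  cusps <- as.matrix(cusps)
  if (ncol(cusps) != 4L) stopf("cusps must have columns x, y, height, width")
  colnames(cusps) <- c("x", "y", "height", "width")
  if (nrow(cusps) > 0) {
    inside <- (abs(cusps[, "x"]) / outline_a)^outline_exp +
      (abs(cusps[, "y"]) / outline_b)^outline_exp
    if (any(inside >= 1)) stopf("cusp position outside the cervical outline")
    if (any(cusps[, "height"] <= 0)) stopf("cusp heights must be positive")
    if (any(cusps[, "width"] <= 0)) stopf("cusp widths must be positive")
  }
  structure(list(outline_a = outline_a, outline_b = outline_b,
                 outline_exp = outline_exp, cusps = cusps,
                 base_height = base_height,
                 mesh_resolution = mesh_resolution),
            class = "tooth_spec")
}

#' @rdname tooth_spec
#' @export
default_cusps <- function() {
  cbind(x = rep(c(-0.85, 0, 0.85), 2),
        y = rep(c(0.45, -0.45), each = 3),
        height = 0.7, width = 0.35)
}

## Smooth taper to zero at the outline so the surface meets the cervical
## plane exactly; identity over the central 85% of the radial range.
taper_profile <- function(rho, start = 0.85) {
  s <- pmin(pmax((rho - start) / (1 - start), 0), 1)
  1 - (3 * s^2 - 2 * s^3)
}

superellipse_radius <- function(phi, a, b, e) {
  (abs(cos(phi) / a)^e + abs(sin(phi) / b)^e)^(-1 / e)
}

crown_height_field <- function(x, y, spec) {
  z <- spec$base_height *
    (1 - pmin((abs(x) / spec$outline_a)^2 + (abs(y) / spec$outline_b)^2, 1))
  if (nrow(spec$cusps) > 0) {
    for (i in seq_len(nrow(spec$cusps))) {
      cu <- spec$cusps[i, ]
      z <- z + cu["height"] *
        exp(-((x - cu["x"])^2 + (y - cu["y"])^2) / (2 * cu["width"]^2))
    }
  }
  z
}

#' Generate a synthetic crown mesh
#'
#' Triangulates the height field implied by a [tooth_spec()] over a polar
#' grid on the superellipse domain: a basal dome plus one Gaussian bump per
#' cusp, tapered so the surface meets z = 0 exactly at the cervical
#' boundary. Deterministic for a given spec.
#'
#' @param spec a [tooth_spec()].
#' @return list with `mesh` (a [tri_mesh()]), `outline` (ordered boundary
#'   points, the cervical line), `outline_indices` and `buccal_anchor`
#'   (the +x boundary point).
#' @export
make_tooth_mesh <- function(spec) {
  stopifnot(inherits(spec, "tooth_spec"))
  ## faces = na + 2 * na * (nr - 1); aim na ~ 2.5 nr
  nr <- max(8L, round(sqrt(spec$mesh_resolution / 5)))
  na <- max(12L, round(2.5 * nr))
  phi <- 2 * pi * (seq_len(na) - 1) / na
  rad <- superellipse_radius(phi, spec$outline_a, spec$outline_b,
                             spec$outline_exp)
  verts <- matrix(0, 1 + nr * na, 3)
  verts[1, ] <- c(0, 0, crown_height_field(0, 0, spec))
  for (i in seq_len(nr)) {
    rho <- i / nr
    x <- rho * rad * cos(phi)
    y <- rho * rad * sin(phi)
    z <- taper_profile(rho) * crown_height_field(x, y, spec)
    if (i == nr) z[] <- 0
    verts[1 + (i - 1) * na + seq_len(na), ] <- cbind(x, y, z)
  }
  idx <- function(i, j) 1 + (i - 1) * na + ((j - 1) %% na) + 1
  faces <- vector("list", nr)
  faces[[1]] <- cbind(1, idx(1, seq_len(na)), idx(1, seq_len(na) + 1))
  for (i in seq_len(nr - 1)) {
    j <- seq_len(na)
    faces[[i + 1]] <- rbind(
      cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  faces <- do.call(rbind, faces)
  mesh <- tri_mesh(verts, faces)
  out_idx <- as.integer(idx(nr, seq_len(na)))
  list(mesh = mesh, outline = verts[out_idx, , drop = FALSE],
       outline_indices = out_idx,
       buccal_anchor = verts[out_idx[1], ])
}

#' Sample a synthetic strain
#'
#' Draws `n` independent perturbations of a crown spec: cusp positions are
#' jittered additively and cusp heights and widths log-normally, with
#' standard deviation `noise`. Reproducible for a given seed.
#'
#' @param spec a [tooth_spec()].
#' @param n number of specimens (>= 1).
#' @param noise non-negative jitter SD (mm for positions; log scale for
#'   heights/widths).
#' @param seed integer RNG seed.
#' @return list of `n` results of [make_tooth_mesh()], each with a `spec`
#'   element recording the perturbed spec.
#' @export
make_strain_sample <- function(spec, n, noise = 0.02, seed = 1) {
  stopifnot(inherits(spec, "tooth_spec"), n >= 1)
  if (noise < 0) stopf("noise SD must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    nc <- nrow(sp$cusps)
    if (nc > 0 && noise > 0) {
      sp$cusps[, "x"] <- sp$cusps[, "x"] + stats::rnorm(nc, 0, noise)
      sp$cusps[, "y"] <- sp$cusps[, "y"] + stats::rnorm(nc, 0, noise)
      sp$cusps[, "height"] <- sp$cusps[, "height"] * exp(stats::rnorm(nc, 0, noise))
      sp$cusps[, "width"] <- sp$cusps[, "width"] * exp(stats::rnorm(nc, 0, noise))
      ## pull any escaped cusp back inside the outline
      r2 <- (abs(sp$cusps[, "x"]) / sp$outline_a)^sp$outline_exp +
        (abs(sp$cusps[, "y"]) / sp$outline_b)^sp$outline_exp
      esc <- r2 >= 0.95
      if (any(esc)) {
        shrink <- (0.9 / r2[esc])^(1 / sp$outline_exp)
        sp$cusps[esc, "x"] <- sp$cusps[esc, "x"] * shrink
        sp$cusps[esc, "y"] <- sp$cusps[esc, "y"] * shrink
      }
    }
    tm <- make_tooth_mesh(sp)
    tm$spec <- sp
    out[[i]] <- tm
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate Brownian-motion traits on a phylogeny
#'
#' Draws `p` independent traits under Brownian motion with rate `sigma2`
#' and root state 0: tip values are multivariate normal with covariance
#' `sigma2 * C`, where `C` holds shared root-to-ancestor path lengths.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param p number of traits.
#' @param sigma2 positive BM rate.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return N x p matrix with tip labels as row names.
#' @export
simulate_bm_traits <- function(tree, p, sigma2 = 1, seed = NULL) {
  if (sigma2 <= 0) stopf("BM rate sigma2 must be positive")
  if (p < 1) stopf("p must be >= 1")
  C <- phylo_covariance(tree)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- nrow(C)
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- t(chol(C)) %*% z * sqrt(sigma2)
  rownames(x) <- rownames(C)
  x
}

#' Icosphere test geometry
#'
#' Unit sphere obtained by subdividing an icosahedron and projecting onto
#' the sphere; used as analytic ground truth (known curvature, normals and
#' section geometry) in tests and examples.
#'
#' @param subdiv number of 4-to-1 subdivisions (0 = icosahedron, 20 faces).
#' @return a [tri_mesh()] with `20 * 4^subdiv` faces.
#' @export
icosphere <- function(subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- unitize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, unitize((v[i, ] + v[j, ]) / 2))
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  tri_mesh(v, f, normals = v)
}
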