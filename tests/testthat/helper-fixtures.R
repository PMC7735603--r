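## Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

## Unit-circle outline points in the z = 0 plane.
circle_outline <- function(n = 72, radius = 1, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(th), radius * sin(th), z)
}

## Oriented hemispherical crown from an icosphere with an equator outline.
hemisphere_crown <- function(subdiv = 4) {
  cached(paste0("hemi", subdiv), function() {
    sph <- icosphere(subdiv)
    orient_and_crop(sph, circle_outline(), buccal_anchor = c(2, 0, 0))
  })
}

## A cone (apex up, half-angle 45 degrees) as an open triangulated surface.
cone_mesh <- function(nr = 60, na = 100) {
  phi <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  v <- rbind(c(0, 0, 1))
  for (i in seq_len(nr)) {
    rho <- i / nr
    v <- rbind(v, cbind(rho * cos(phi), rho * sin(phi), 1 - rho))
  }
  idx <- function(i, j) 1 + (i - 1) * na + ((j - 1) %% na) + 1
  f <- cbind(1, idx(1, 1:na), idx(1, 1:na + 1))
  for (i in seq_len(nr - 1)) {
    j <- 1:na
    f <- rbind(f, cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  list(mesh = tri_mesh(v, f), outline = v[idx(nr, 1:na), ],
       anchor = c(2, 0, 0))
}

## Build a map_set by hand from matrices (for unit tests of the algebra).
manual_mapset <- function(maps, normalized = FALSE, weighted = FALSE,
                          id = "m", group = "g") {
  K <- nrow(maps[[1]]); L <- ncol(maps[[1]])
  structure(list(maps = maps, specimen_id = id, group = group,
                 grid_K = K, grid_L = L, centroid_size = NA_real_,
                 normalized = normalized, weighted = weighted),
            class = "map_set")
}

## Three synthetic strains with distinct cusp patterns (6, 4 and 2 cusps).
strain_specs <- function() {
  list(
    strain6 = tooth_spec(),
    strain4 = tooth_spec(cusps = cbind(x = c(-0.7, 0.7, -0.7, 0.7),
                                       y = c(0.4, 0.4, -0.4, -0.4),
                                       height = 0.7, width = 0.4)),
    strain2 = tooth_spec(cusps = cbind(x = c(-0.6, 0.6), y = c(0, 0),
                                       height = 0.8, width = 0.5),
                         outline_b = 0.9))
}

## n specimens per strain as normalized map sets on a small grid.
strain_mapsets <- function(n = 4, grid = 32, noise = 0.02) {
  key <- sprintf("strains_%d_%d_%g", n, grid, noise)
  cached(key, function() {
    specs <- strain_specs()
    out <- list()
    for (s in seq_along(specs)) {
      samp <- make_strain_sample(specs[[s]], n, noise = noise, seed = 100 + s)
      for (i in seq_along(samp)) {
        sp <- samp[[i]]
        sp$specimen_id <- sprintf("%s_%02d", names(specs)[s], i)
        sp$group <- names(specs)[s]
        out[[length(out) + 1L]] <-
          specimens_to_mapsets(list(sp), grid, grid)[[1]]
      }
    }
    out
  })
}

## Random rigid motion (rotation + translation), deterministic per seed.
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- crownmap:::rotation_between(c(0, 0, 1), ax) %*%
    crownmap:::rotation_z(runif(1, 0, 2 * pi))
  list(R = R, t = rnorm(3, 0, 2))
}

apply_rigid <- function(points, rig) {
  points %*% t(rig$R) + rep(rig$t, each = nrow(points))
}

## Compare two vertex sets up to permutation: max nearest-neighbour distance.
vertex_set_distance <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  d <- 0
  for (i in seq_len(nrow(a))) {
    di <- sqrt(colSums((t(b) - a[i, ])^2))
    d <- max(d, min(di))
  }
  d
}
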