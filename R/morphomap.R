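#' Radially sample an oriented crown
#'
#' Sections the crown surface by `grid_L` equiangular vertical half-planes
#' through the z axis (azimuth `anatomical_zero + 2*pi*(l-1)/L`, so column 1
#' starts at the buccal direction) and samples `grid_K` points along each
#' section curve at equal arc-length intervals, from the curve's innermost
#' point (nearest the z axis, d = 0) to its endpoint on the cervical cut
#' plane z = 0 (d = 1). When a half-plane intersects the surface in several
#' curve components (overhangs), the component ending on z = 0 with the
#' largest mean radius is kept.
#'
#' @param crown an [orient_and_crop()] result.
#' @param grid_K radial samples per section (default 300).
#' @param grid_L number of angular sections (default 300).
#' @return a `sample_grid`: list of K x L arrays `points` (xyz), `normals`
#'   (unit, edge-interpolated), `curvature`, `tri` (containing-triangle id),
#'   plus `grid_K`, `grid_L`.
#' @export
radial_sample <- function(crown, grid_K = 300, grid_L = 300) {
  stopifnot(inherits(crown, "oriented_crown"))
  if (grid_K < 2 || grid_L < 2) stopf("grid_K and grid_L must be >= 2")
  mesh <- crown$mesh
  v <- mesh$vertices; f <- mesh$faces
  curv <- mean_curvature(mesh)
  attrs <- cbind(mesh$normals, curv) # per-vertex: nx ny nz c
  scale <- max(vnorm(apply(v, 2, max) - apply(v, 2, min)), .Machine$double.eps)
  eps <- 1e-12 * scale

  K <- as.integer(grid_K); L <- as.integer(grid_L)
  P <- array(NA_real_, c(K, L, 3))
  N <- array(NA_real_, c(K, L, 3))
  Cm <- matrix(NA_real_, K, L)
  Tm <- matrix(NA_integer_, K, L)

  for (l in seq_len(L)) {
    theta <- crown$anatomical_zero + 2 * pi * (l - 1) / L
    sec <- section_curve(v, f, attrs, theta, eps, scale)
    if (is.null(sec))
      stopf("section %d (azimuth %.4f rad) does not intersect the surface from the z axis to the cervix", l, theta)
    sm <- sample_section(sec, K)
    P[, l, ] <- sm$points
    N[, l, ] <- sm$normals
    Cm[, l] <- sm$curvature
    Tm[, l] <- sm$tri
  }
  structure(list(points = P, normals = N, curvature = Cm, tri = Tm,
                 grid_K = K, grid_L = L),
            class = "sample_grid")
}

## Intersect the mesh with the vertical half-plane at azimuth theta.
## Returns the selected component as an ordered list of segments
## (positions, attributes, triangle ids, cumulative arc length), or NULL.
section_curve <- function(v, f, attrs, theta, eps, scale) {
  dir2 <- c(cos(theta), sin(theta))
  s <- v[, 1] * (-dir2[2]) + v[, 2] * dir2[1] # signed dist to section plane
  s[abs(s) < eps] <- eps                       # nudge on-plane vertices
  pos <- s > 0
  cr <- which(xor(pos[f[, 1]], pos[f[, 2]]) | xor(pos[f[, 2]], pos[f[, 3]]))
  if (length(cr) == 0L) return(NULL)

  seg_p1 <- NULL
  ## for each crossing triangle find its two crossed edges
  edge_pt <- function(i, j) {
    w <- s[i] / (s[i] - s[j])
    p <- v[i, , drop = FALSE] * (1 - w) + v[j, , drop = FALSE] * w
    a <- attrs[i, , drop = FALSE] * (1 - w) + attrs[j, , drop = FALSE] * w
    list(p = p, a = a)
  }
  P1 <- matrix(0, length(cr), 3); P2 <- P1
  A1 <- matrix(0, length(cr), 4); A2 <- A1
  for (k in seq_along(cr)) {
    tri <- f[cr[k], ]
    ss <- pos[tri]
    ## edges with sign change
    pr <- rbind(c(1, 2), c(2, 3), c(3, 1))
    ce <- pr[xor(ss[pr[, 1]], ss[pr[, 2]]), , drop = FALSE]
    e1 <- edge_pt(tri[ce[1, 1]], tri[ce[1, 2]])
    e2 <- edge_pt(tri[ce[2, 1]], tri[ce[2, 2]])
    P1[k, ] <- e1$p; A1[k, ] <- e1$a
    P2[k, ] <- e2$p; A2[k, ] <- e2$a
  }
  ## radial coordinate along the half-plane; clip at t = 0 (keep t >= 0)
  t1 <- P1[, 1] * dir2[1] + P1[, 2] * dir2[2]
  t2 <- P2[, 1] * dir2[1] + P2[, 2] * dir2[2]
  keep <- !(t1 < 0 & t2 < 0)
  clip_one <- function(Pa, Aa, ta, Pb, Ab, tb, k) {
    ## replace endpoint a (t<0) by the t=0 crossing of segment k
    u <- ta[k] / (ta[k] - tb[k])
    Pa[k, ] <- Pa[k, ] * (1 - rep(u, 3)) + Pb[k, ] * rep(u, 3)
    Aa[k, ] <- Aa[k, ] * (1 - rep(u, 4)) + Ab[k, ] * rep(u, 4)
    list(P = Pa, A = Aa)
  }
  for (k in which(t1 < 0 & t2 >= 0)) {
    r <- clip_one(P1, A1, t1, P2, A2, t2, k); P1 <- r$P; A1 <- r$A
  }
  for (k in which(t2 < 0 & t1 >= 0)) {
    r <- clip_one(P2, A2, t2, P1, A1, t1, k); P2 <- r$P; A2 <- r$A
  }
  P1 <- P1[keep, , drop = FALSE]; P2 <- P2[keep, , drop = FALSE]
  A1 <- A1[keep, , drop = FALSE]; A2 <- A2[keep, , drop = FALSE]
  tris <- cr[keep]
  len <- sqrt(rowSums((P2 - P1)^2))
  ok <- len > 1e-10 * scale
  P1 <- P1[ok, , drop = FALSE]; P2 <- P2[ok, , drop = FALSE]
  A1 <- A1[ok, , drop = FALSE]; A2 <- A2[ok, , drop = FALSE]
  tris <- tris[ok]; len <- len[ok]
  ns <- nrow(P1)
  if (ns == 0L) return(NULL)

  ## chain segments into polylines by endpoint proximity
  key <- function(p) paste(round(p[, 1] / (1e-7 * scale)),
                           round(p[, 2] / (1e-7 * scale)),
                           round(p[, 3] / (1e-7 * scale)))
  k1 <- key(P1); k2 <- key(P2)
  nodes <- unique(c(k1, k2))
  n1 <- match(k1, nodes); n2 <- match(k2, nodes)
  ## adjacency: for each node, incident segments
  inc <- split(rep(seq_len(ns), 2), c(n1, n2))
  deg <- lengths(inc)
  used <- logical(ns)
  comps <- list()
  start_nodes <- as.integer(names(deg)[deg == 1])
  for (sn in start_nodes) {
    seg0 <- inc[[as.character(sn)]][1]
    if (used[seg0]) next
    path <- integer(0); flip <- logical(0)
    node <- sn; seg <- seg0
    repeat {
      used[seg] <- TRUE
      path <- c(path, seg)
      fl <- n2[seg] == node # entering via P2 -> traverse reversed
      flip <- c(flip, fl)
      node <- if (fl) n1[seg] else n2[seg]
      nxt <- setdiff(inc[[as.character(node)]], which(used))
      if (length(nxt) == 0L) break
      seg <- nxt[1]
    }
    comps[[length(comps) + 1L]] <- list(path = path, flip = flip)
  }
  if (length(comps) == 0L) return(NULL)

  ztol <- 1e-7 * scale
  build <- function(cmp) {
    p_start <- ifelse(cmp$flip, list(NULL), list(NULL)) # placeholder
    a_pos <- lapply(seq_along(cmp$path), function(i) {
      k <- cmp$path[i]
      if (cmp$flip[i]) list(p1 = P2[k, ], p2 = P1[k, ], a1 = A2[k, ], a2 = A1[k, ], tri = tris[k])
      else list(p1 = P1[k, ], p2 = P2[k, ], a1 = A1[k, ], a2 = A2[k, ], tri = tris[k])
    })
    a_pos
  }
  cands <- list()
  for (cmp in comps) {
    segs <- build(cmp)
    first <- segs[[1]]$p1; last <- segs[[length(segs)]]$p2
    end_on_cut <- abs(last[3]) < ztol
    start_on_cut <- abs(first[3]) < ztol
    if (!end_on_cut && !start_on_cut) next
    if (!end_on_cut && start_on_cut) {
      ## reverse so the z=0 endpoint is last
      segs <- rev(lapply(segs, function(sg)
        list(p1 = sg$p2, p2 = sg$p1, a1 = sg$a2, a2 = sg$a1, tri = sg$tri)))
    } else if (end_on_cut && start_on_cut) {
      ## both ends at the cervix: orient from the innermost end
      r_first <- vnorm(first[1:2]); r_last <- vnorm(last[1:2])
      if (r_first < r_last) {
        ## already innermost-first
      } else {
        segs <- rev(lapply(segs, function(sg)
          list(p1 = sg$p2, p2 = sg$p1, a1 = sg$a2, a2 = sg$a1, tri = sg$tri)))
      }
    }
    pts <- do.call(rbind, lapply(segs, function(sg) sg$p1))
    mean_r <- mean(sqrt(pts[, 1]^2 + pts[, 2]^2))
    cands[[length(cands) + 1L]] <- list(segs = segs, mean_r = mean_r)
  }
  if (length(cands) == 0L) return(NULL)
  best <- cands[[which.max(vapply(cands, `[[`, 0, "mean_r"))]]
  segs <- best$segs
  lens <- vapply(segs, function(sg) vnorm(sg$p2 - sg$p1), 0)
  list(segs = segs, cum = cumsum(c(0, lens)), total = sum(lens))
}

## Sample K points at equal arc length along a section curve.
sample_section <- function(sec, K) {
  targets <- sec$total * (seq_len(K) - 1) / (K - 1)
  pts <- matrix(0, K, 3); nr <- matrix(0, K, 3)
  cv <- numeric(K); tr <- integer(K)
  cum <- sec$cum
  for (k in seq_len(K)) {
    s <- targets[k]
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(sec$segs))
    sg <- sec$segs[[i]]
    seg_len <- cum[i + 1] - cum[i]
    u <- if (seg_len > 0) (s - cum[i]) / seg_len else 0
    pts[k, ] <- sg$p1 * (1 - u) + sg$p2 * u
    a <- sg$a1 * (1 - u) + sg$a2 * u
    nr[k, ] <- unitize(a[1:3])
    cv[k] <- a[4]
    tr[k] <- sg$tri
  }
  ## the last target is the exact curve endpoint on z = 0
  pts[K, 3] <- 0
  list(points = pts, normals = nr, curvature = cv, tri = tr)
}

#' Compute the six morphometric maps of a specimen
#'
#' From a [radial_sample()] grid: `h` = height above the cervical plane,
#' `r` = horizontal radius from the centroid axis, `Nx`,`Ny`,`Nz` = unit
#' vertex normal interpolated at the sample point, `c` = discrete mean
#' curvature ([mean_curvature()]) interpolated at the sample point.
#'
#' @param grid a `sample_grid`.
#' @param crown the `oriented_crown` the grid was sampled from.
#' @param specimen_id,group optional labels carried through the pipeline.
#' @return a `map_set`: named list of K x L matrices `c`, `h`, `r`, `Nx`,
#'   `Ny`, `Nz` plus metadata (`grid_K`, `grid_L`, `centroid_size`,
#'   `normalized`, `weighted`).
#' @export
compute_parameter_maps <- function(grid, crown, specimen_id = NA_character_,
                                   group = NA_character_) {
  stopifnot(inherits(grid, "sample_grid"))
  h <- grid$points[, , 3]
  h[abs(h) < 1e-12] <- 0
  r <- sqrt(grid$points[, , 1]^2 + grid$points[, , 2]^2)
  structure(list(
    maps = list(c = grid$curvature, h = h, r = r,
                Nx = grid$normals[, , 1], Ny = grid$normals[, , 2],
                Nz = grid$normals[, , 3]),
    specimen_id = specimen_id, group = group,
    grid_K = grid$grid_K, grid_L = grid$grid_L,
    centroid_size = NA_real_, normalized = FALSE, weighted = FALSE),
    class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("map_set [%s]: %d x %d, CS = %s, normalized = %s, weighted = %s\n",
              x$specimen_id %||% "?", x$grid_K, x$grid_L,
              format(x$centroid_size), x$normalized, x$weighted))
  invisible(x)
}

#' Centroid-size normalization of a map set
#'
#' Centroid size is `CS = sqrt(sum(h^2 + r^2))` over all K x L samples.
#' `h` and `r` are divided by CS, curvature `c` is multiplied by CS (it
#' scales as 1/length), and the normal maps are unchanged.
#'
#' @param maps an unweighted `map_set`.
#' @return the normalized `map_set` with `centroid_size` recorded.
#' @export
centroid_size_normalize <- function(maps) {
  stopifnot(inherits(maps, "map_set"))
  if (maps$weighted) stopf("normalize before applying area weights")
  if (maps$normalized) stopf("map set already centroid-size normalized")
  cs <- sqrt(sum(maps$maps$h^2 + maps$maps$r^2))
  if (cs == 0) stopf("degenerate map set: centroid size is zero")
  maps$maps$h <- maps$maps$h / cs
  maps$maps$r <- maps$maps$r / cs
  maps$maps$c <- maps$maps$c * cs
  maps$centroid_size <- cs
  maps$normalized <- TRUE
  maps
}

#' Concentric area weights on the unit disk
#'
#' Cell (k, l) receives the area of the annular sector between radii
#' `(k-1)/K` and `k/K` spanning angle `2*pi/L`:
#' `a_kl = pi * ((k/K)^2 - ((k-1)/K)^2) / L`, constant across columns.
#' Weights sum to `pi`, the unit-disk area.
#'
#' @param grid_K,grid_L grid dimensions.
#' @return K x L matrix of cell areas.
#' @export
area_weight_matrix <- function(grid_K, grid_L) {
  if (grid_K < 1 || grid_L < 1) stopf("grid dims must be >= 1")
  k <- seq_len(grid_K)
  a <- pi * ((k / grid_K)^2 - ((k - 1) / grid_K)^2) / grid_L
  matrix(a, grid_K, grid_L)
}

#' Apply concentric area weights to a map set
#'
#' Each cell is multiplied by `sqrt(a_kl / pi)` so that the plain Euclidean
#' distance between two weighted maps equals the square root of the
#' area-weighted mean squared difference of the raw maps.
#'
#' @param maps an unweighted `map_set`.
#' @param weights optional K x L weight matrix; defaults to
#'   [area_weight_matrix()] for the set's grid.
#' @return the weighted `map_set`.
#' @export
apply_weights <- function(maps, weights = NULL) {
  stopifnot(inherits(maps, "map_set"))
  if (maps$weighted) stopf("area weights already applied to this map set")
  if (is.null(weights)) weights <- area_weight_matrix(maps$grid_K, maps$grid_L)
  if (!all(dim(weights) == c(maps$grid_K, maps$grid_L)))
    stopf("weight matrix does not match the grid")
  w <- sqrt(weights / pi)
  maps$maps <- lapply(maps$maps, function(m) m * w)
  maps$weighted <- TRUE
  maps
}

#' Render a morphometric map as an RGB raster
#'
#' Scalar maps use the viridis colormap over their value range; the vertex
#' normal is rendered with (Nx, Ny, Nz) linearly mapped from \[-1, 1\] to
#' \[0, 255\] as (R, G, B). When a `map_set` is given, the image is padded
#' at the outer edge so each column's drawn length follows the relative
#' cervical radius, mirroring the crown outline.
#'
#' @param map a `map_set`, or a plain K x L matrix.
#' @param parameter which map to render from a set: one of `c`, `h`, `r`,
#'   or `"Nxyz"` for the combined normal image.
#' @param pad pad columns to the relative cervical radius (map sets only).
#' @param background background value in \[0, 1\] used for padding.
#' @return K x L x 3 numeric array in \[0, 1\], quantized to 1/255 steps.
#' @export
render_map <- function(map, parameter = "Nxyz", pad = TRUE, background = 1) {
  if (inherits(map, "map_set")) {
    if (map$weighted) stopf("render unweighted maps")
    if (parameter == "Nxyz") {
      img <- array(NA_real_, c(map$grid_K, map$grid_L, 3))
      img[, , 1] <- encode_unit(map$maps$Nx)
      img[, , 2] <- encode_unit(map$maps$Ny)
      img[, , 3] <- encode_unit(map$maps$Nz)
    } else {
      img <- colormap_rgb(map$maps[[parameter]])
    }
    if (pad) {
      rel <- map$maps$r[map$grid_K, ]
      rel <- rel / max(rel)
      img <- pad_columns(img, rel, background)
    }
    img
  } else {
    colormap_rgb(as.matrix(map))
  }
}

encode_unit <- function(m) round((m + 1) / 2 * 255) / 255

colormap_rgb <- function(m, n = 256L) {
  pal <- grDevices::hcl.colors(n, "viridis")
  rng <- range(m, finite = TRUE)
  idx <- if (diff(rng) == 0) rep(1L, length(m))
         else pmin(pmax(1L + as.integer((m - rng[1]) / diff(rng) * (n - 1L)), 1L), n)
  col <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(NA_real_, c(nrow(m), ncol(m), 3))
  out[, , 1] <- matrix(col[1, ], nrow(m)); out[, , 2] <- matrix(col[2, ], nrow(m))
  out[, , 3] <- matrix(col[3, ], nrow(m))
  out
}

pad_columns <- function(img, rel, background) {
  K <- dim(img)[1]
  out <- array(background, dim(img))
  for (l in seq_len(dim(img)[2])) {
    nl <- max(1L, round(K * rel[l]))
    src <- round(seq(1, K, length.out = nl))
    out[seq_len(nl), l, ] <- img[src, l, ]
  }
  out
}
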