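#' Discrete mean curvature at mesh vertices
#'
#' Cotangent-Laplacian mean-curvature estimator: the magnitude of the
#' discrete mean-curvature normal (Laplace-Beltrami of the coordinates over
#' twice the barycentric vertex area), signed positive where the surface is
#' convex with respect to the outward vertex normal. A unit sphere with
#' outward normals gives +1 everywhere.
#'
#' Curvature is undefined on the one-ring of a boundary vertex; boundary
#' values are filled by iteratively averaging interior neighbours so that
#' interpolation near the crown base stays finite.
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector, one curvature per vertex.
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]

  cot_angle <- function(a, b, cc) {
    ## cotangent of angle at a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cr <- sqrt(rowSums(cross3_rows(u, w)^2))
    dt / pmax(cr, 1e-300)
  }
  c1 <- cot_angle(i1, i2, i3) # weights edge (i2,i3)
  c2 <- cot_angle(i2, i3, i1) # weights edge (i3,i1)
  c3 <- cot_angle(i3, i1, i2) # weights edge (i1,i2)

  ## accumulate L x_i = sum_j w_ij (x_j - x_i), w_ij = (cot a + cot b)/2
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- c(c1, c1, c2, c2, c3, c3) / 2
  lap <- matrix(0, nv, 3)
  wsum_used <- rowsum(cbind(ww * (v[jj, 1] - v[ii, 1]),
                            ww * (v[jj, 2] - v[ii, 2]),
                            ww * (v[jj, 3] - v[ii, 3])), group = ii,
                      reorder = FALSE)
  lap[as.integer(rownames(wsum_used)), ] <- wsum_used

  area <- face_areas(v, f)
  A <- numeric(nv)
  for (j in 1:3) {
    acc <- rowsum(area / 3, group = f[, j], reorder = FALSE)
    A[as.integer(rownames(acc))] <- A[as.integer(rownames(acc))] + acc[, 1]
  }
  A[A == 0] <- Inf

  hvec <- lap / (2 * A)
  mag <- sqrt(rowSums(hvec^2))
  sgn <- ifelse(rowSums(hvec * mesh$normals) <= 0, 1, -1)
  curv <- mag * sgn

  ## fill boundary vertices from interior neighbours
  bnd <- boundary_vertices(f, nv)
  if (any(bnd)) {
    adj_i <- c(i1, i2, i2, i3, i3, i1)
    adj_j <- c(i2, i1, i3, i2, i1, i3)
    curv[bnd] <- NA_real_
    for (iter in 1:50) {
      nas <- which(is.na(curv))
      if (length(nas) == 0L) break
      sel <- adj_i %in% nas & !is.na(curv[adj_j])
      if (!any(sel)) break
      mn <- rowsum(curv[adj_j[sel]], group = adj_i[sel], reorder = FALSE)
      ct <- rowsum(rep(1, sum(sel)), group = adj_i[sel], reorder = FALSE)
      ids <- as.integer(rownames(mn))
      curv[ids] <- mn[, 1] / ct[, 1]
    }
    curv[is.na(curv)] <- 0
  }
  curv
}

## Logical vector marking vertices on a boundary edge (edge used by exactly
## one face).
boundary_vertices <- function(faces, nv) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- names(which(table(key) == 1L))
  out <- logical(nv)
  if (length(single)) {
    ids <- unlist(strsplit(single, " "))
    out[as.integer(ids)] <- TRUE
  }
  out
}
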