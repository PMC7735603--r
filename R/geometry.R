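#' Least-squares plane of a cervical outline
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' outline points (total least squares via the singular value decomposition
#' of the centered point cloud).
#'
#' @param outline numeric k x 3 matrix of ordered outline points (k >= 3,
#'   not collinear).
#' @param toward optional 3D point; the normal is flipped so this point lies
#'   on the positive side (used to point the normal at the crown).
#' @return list with unit `normal` and scalar `offset` such that the plane
#'   is \{x : normal . x = offset\}; class `cervical_plane`.
#' @export
fit_cervical_plane <- function(outline, toward = NULL) {
  pts <- as.matrix(outline)
  if (nrow(pts) < 3L) stopf("cervical outline needs at least 3 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-10 * max(sv$d[1], .Machine$double.eps))
    stopf("outline points are collinear; plane is undetermined")
  normal <- sv$v[, 3]
  if (!is.null(toward) && sum(normal * (toward - ctr)) < 0) normal <- -normal
  structure(list(normal = normal, offset = sum(normal * ctr)),
            class = "cervical_plane")
}

## Exact clip of a triangle mesh at z = 0, keeping z >= 0. Triangles
## crossing the plane are split; new vertices get z exactly 0. Vertex
## normals are re-used for original vertices and edge-interpolated for
## cut vertices, so sampled normals are continuous across the cut.
clip_mesh_z <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces; nrm <- mesh$normals
  z <- v[, 3]
  eps <- 1e-12 * max(abs(z), 1)
  above <- z >= -eps
  keep_all <- above[f[, 1]] & above[f[, 2]] & above[f[, 3]]
  drop_all <- (!above[f[, 1]]) & (!above[f[, 2]]) & (!above[f[, 3]])
  cross_f <- which(!keep_all & !drop_all)

  new_v <- list(); new_n <- list(); new_f <- list()
  cut_cache <- new.env(hash = TRUE)
  n0 <- nrow(v)
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    id <- cut_cache[[key]]
    if (!is.null(id)) return(id)
    t <- z[i] / (z[i] - z[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p[3] <- 0 # exact by construction
    nn <- unitize((1 - t) * nrm[i, ] + t * nrm[j, ])
    new_v[[length(new_v) + 1L]] <<- p
    new_n[[length(new_n) + 1L]] <<- nn
    id <- n0 + length(new_v)
    cut_cache[[key]] <- id
    id
  }

  for (fi in cross_f) {
    tri <- f[fi, ]
    up <- tri[above[tri]]
    dn <- tri[!above[tri]]
    if (length(up) == 1L) {
      a <- up[1]; b <- dn[1]; cc <- dn[2]
      ## preserve winding: find positions
      p1 <- cut_point(a, b); p2 <- cut_point(a, cc)
      ## original order around triangle determines orientation; re-derive
      ord <- tri
      ia <- which(ord == a)
      nxt <- ord[ia %% 3 + 1]
      if (nxt == b) new_f[[length(new_f) + 1L]] <- c(a, p1, p2)
      else          new_f[[length(new_f) + 1L]] <- c(a, p2, p1)
    } else {
      a <- up[1]; b <- up[2]; cc <- dn[1]
      p1 <- cut_point(a, cc); p2 <- cut_point(b, cc)
      ord <- tri
      ia <- which(ord == a)
      nxt <- ord[ia %% 3 + 1]
      if (nxt == b) {
        new_f[[length(new_f) + 1L]] <- c(a, b, p2)
        new_f[[length(new_f) + 1L]] <- c(a, p2, p1)
      } else {
        new_f[[length(new_f) + 1L]] <- c(b, a, p1)
        new_f[[length(new_f) + 1L]] <- c(b, p1, p2)
      }
    }
  }

  v2 <- rbind(v, do.call(rbind, new_v))
  n2 <- rbind(nrm, do.call(rbind, new_n))
  f2 <- rbind(f[keep_all, , drop = FALSE],
              do.call(rbind, lapply(new_f, as.integer)))
  ## drop unreferenced vertices
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2)); remap[used] <- seq_along(used)
  structure(list(vertices = v2[used, , drop = FALSE],
                 faces = matrix(remap[f2], ncol = 3),
                 normals = n2[used, , drop = FALSE]),
            class = "tri_mesh")
}

#' Place a crown mesh in the standard coordinate system
#'
#' Rotates and translates the mesh so that the least-squares cervical plane
#' becomes z = 0 with the crown on the positive side, the cervical-outline
#' centroid sits on the z axis, and the buccal anchor points along +x. The
#' model is then shifted down so that exactly the upper 80% of crown height
#' (highest cusp tip to cervical plane) lies above z = 0, and cropped at
#' z = 0 by an exact plane clip.
#'
#' @param mesh a [tri_mesh()].
#' @param outline k x 3 matrix of ordered cervical-outline points.
#' @param buccal_anchor 3D point marking the buccal side (must not project
#'   onto the z axis).
#' @param keep_fraction fraction of crown height kept above the cut
#'   (default 0.8).
#' @return an `oriented_crown`: list with `mesh` (cropped, standard pose),
#'   `outline` (transformed cervical outline), `crown_height`,
#'   `anatomical_zero` (azimuth of the buccal direction, 0 by construction)
#'   and the applied `rotation`/`translation`.
#' @export
orient_and_crop <- function(mesh, outline, buccal_anchor,
                            keep_fraction = 0.8) {
  outline <- as.matrix(outline)
  ctr_mesh <- colMeans(mesh$vertices)
  plane <- fit_cervical_plane(outline, toward = ctr_mesh)

  R1 <- rotation_between(plane$normal, c(0, 0, 1))
  o_ctr <- colMeans(outline)
  xf <- function(p, R) {
    p <- as.matrix(p)
    sweep(p, 2, o_ctr) %*% t(R)
  }
  v1 <- xf(mesh$vertices, R1)
  anchor1 <- drop(xf(matrix(buccal_anchor, 1), R1))
  if (vnorm(anchor1[1:2]) < 1e-9 * max(1, vnorm(anchor1)))
    stopf("buccal anchor projects onto the z axis; azimuth undetermined")
  phi <- atan2(anchor1[2], anchor1[1])
  R <- rotation_z(-phi) %*% R1
  v <- xf(mesh$vertices, R)
  out_pts <- xf(outline, R)
  nrm <- mesh$normals %*% t(R)

  ## plane is now z = mean(out_pts z) ~ 0 (outline centroid at origin);
  ## residual outline z is plane-fit noise, by construction 0-mean
  H <- max(v[, 3])
  if (H <= 0) stopf("crown lies entirely below the cervical plane")
  ## an already-cropped crown floats (1 - keep_fraction) * H above its
  ## cervical plane, so only flag clearly detached outlines
  if (min(v[, 3]) > 0.3 * H)
    stopf("cervical plane does not touch the mesh: the outline is detached from the crown base")
  shift <- (1 - keep_fraction) * H
  v[, 3] <- v[, 3] - shift
  out_pts[, 3] <- out_pts[, 3] - shift

  posed <- structure(list(vertices = v, faces = mesh$faces, normals = nrm),
                     class = "tri_mesh")
  cropped <- clip_mesh_z(posed)
  if (nrow(cropped$faces) == 0L) stopf("degenerate crown: nothing above the cut")
  structure(list(mesh = cropped, outline = out_pts, crown_height = H,
                 anatomical_zero = 0,
                 rotation = R, translation = -drop(o_ctr %*% t(R)) - c(0, 0, shift)),
            class = "oriented_crown")
}

#' @export
print.oriented_crown <- function(x, ...) {
  cat(sprintf(
    "oriented_crown: %d vertices, crown height %.4g, cut at z = 0 (top %.4g)\n",
    nrow(x$mesh$vertices), x$crown_height, max(x$mesh$vertices[, 3])))
  invisible(x)
}
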