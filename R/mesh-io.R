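#' Triangle mesh constructor
#'
#' Builds a triangle-mesh object from a vertex matrix and a face index
#' matrix, computing area-weighted unit vertex normals when none are given.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of vertex normals; renormalized.
#' @return An object of class `tri_mesh`: a list with elements `vertices`,
#'   `faces` and `normals`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3")
  if (ncol(faces) != 3L) stopf("faces must be m x 3")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stopf("empty mesh")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stopf("face indices out of range (1..%d)", nrow(vertices))
  if (is.null(normals)) {
    normals <- vertex_normals(vertices, faces)
  } else {
    normals <- unitize_rows(as.matrix(normals))
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Area-weighted unit vertex normals
#'
#' @param vertices n x 3 vertex matrix.
#' @param faces m x 3 face index matrix.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  fn <- cross3_rows(b - a, cc - a) # length = 2 * face area
  nrm <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = faces[, j], reorder = FALSE)
      nrm[as.integer(rownames(acc)), d] <- nrm[as.integer(rownames(acc)), d] + acc[, 1]
    }
  }
  unitize_rows(nrm)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  fn <- cross3_rows(b - a, cc - a)
  0.5 * sqrt(rowSums(fn^2))
}

## Merge vertices closer than `tol` (relative to the bounding-box diagonal),
## remapping faces and dropping degenerate triangles. STL stores one vertex
## triple per facet, so merging is required to recover shared topology.
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  diag_len <- vnorm(apply(vertices, 2, max) - apply(vertices, 2, min))
  if (diag_len == 0) diag_len <- 1
  key <- apply(round(vertices / (diag_len * tol)), 1,
               function(r) paste(r, collapse = "_"))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(newid[faces], ncol = 3)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  list(vertices = vertices, faces = faces[!degen, , drop = FALSE])
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' ASCII and binary little-endian PLY, ASCII OBJ, and ASCII or binary STL
#' are supported. STL facets are merged back into shared vertices.
#'
#' @param path mesh file; format taken from the extension.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stopf("unsupported mesh format: .%s", ext))
  if (nrow(m$vertices) == 0L || nrow(m$faces) == 0L)
    stopf("empty mesh: %s", path)
  tri_mesh(m$vertices, m$faces)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("truncated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stopf("not a PLY file: %s", path)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stopf("unsupported PLY format: %s", fmt)
  ## parse element/property declarations
  elems <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, ctype = tok[3], vtype = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, vtype = tok[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stopf("PLY lacks vertex/face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(vtype, n = 1L) {
    sz <- type_size[[vtype]]
    if (vtype %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", vtype)))
  }

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    nv <- elems$vertex$count
    vtoks <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    pnames <- vapply(elems$vertex$props, `[[`, "", "name")
    vmat <- do.call(rbind, lapply(vtoks, function(t) as.numeric(t)))
    xyz <- vmat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    ftoks <- strsplit(trimws(body[nv + seq_len(elems$face$count)]), "\\s+")
    faces <- do.call(rbind, lapply(ftoks, function(t) {
      t <- as.integer(t)
      if (t[1] != 3L) stopf("only triangular PLY faces are supported")
      t[2:4] + 1L
    }))
  } else {
    nv <- elems$vertex$count
    pnames <- vapply(elems$vertex$props, `[[`, "", "name")
    vtypes <- vapply(elems$vertex$props, `[[`, "", "vtype")
    vmat <- matrix(NA_real_, nv, length(pnames))
    for (i in seq_len(nv))
      for (j in seq_along(pnames))
        vmat[i, j] <- read_scalar(vtypes[j])
    xyz <- vmat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    fp <- elems$face$props[[1]]
    faces <- matrix(NA_integer_, elems$face$count, 3)
    for (i in seq_len(elems$face$count)) {
      cnt <- read_scalar(fp$ctype)
      if (cnt != 3L) stopf("only triangular PLY faces are supported")
      faces[i, ] <- read_scalar(fp$vtype, 3L) + 1L
    }
  }
  if (anyNA(xyz)) stopf("PLY vertex element lacks x/y/z properties")
  list(vertices = xyz, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    idx <- as.integer(sub("/.*$", "", t[-1]))
    if (length(idx) != 3L) stopf("only triangular OBJ faces are supported")
    idx
  }))
  m <- merge_vertices(verts, faces)
  list(vertices = m$vertices, faces = m$faces)
}

read_stl <- function(path) {
  ## binary STL: 80-byte header, uint32 facet count, 50 bytes per facet
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(n) && sz == 84 + 50 * as.numeric(n)) is_binary <- TRUE
  }
  if (is_binary) {
    tri <- matrix(NA_real_, 0, 3)
    vlist <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L) # attribute byte count
      vlist[[i]] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    verts <- do.call(rbind, vlist)
  } else {
    close(con); on.exit(NULL)
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- lines[startsWith(lines, "vertex")]
    verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                                   function(t) as.numeric(t[2:4])))
  }
  nfv <- nrow(verts)
  if (is.null(nfv) || nfv %% 3 != 0) stopf("malformed STL: %s", path)
  faces <- matrix(seq_len(nfv), ncol = 3, byrow = TRUE)
  m <- merge_vertices(verts, faces)
  list(vertices = m$vertices, faces = m$faces)
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output file; format from extension.
#' @param binary write the binary variant (PLY, STL); OBJ is ASCII only.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(c("ply", "format binary_little_endian 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property float x", "property float y", "property float z",
                   sprintf("element face %d", nrow(f)),
                   "property list uchar int vertex_indices", "end_header"),
                 con, sep = "\n")
      writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    } else {
      head <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
      vtxt <- apply(v, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
      ftxt <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
      writeLines(c(head, vtxt, ftxt), path)
    }
  } else if (ext == "obj") {
    vtxt <- apply(v, 1, function(r) paste(c("v", sprintf("%.9g", r)), collapse = " "))
    ftxt <- apply(f, 1, function(r) paste(c("f", r), collapse = " "))
    writeLines(c(vtxt, ftxt), path)
  } else if (ext == "stl") {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    fn <- unitize_rows(cross3_rows(b - a, cc - a))
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80L), con)
      writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(c(fn[i, ], a[i, ], b[i, ], cc[i, ]), con, size = 4L,
                 endian = "little")
        writeBin(raw(2L), con)
      }
    } else {
      out <- c("solid crownmap")
      for (i in seq_len(nrow(f))) {
        out <- c(out,
                 sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                 "outer loop",
                 sprintf("vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
                 sprintf("vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
                 sprintf("vertex %.9g %.9g %.9g", cc[i, 1], cc[i, 2], cc[i, 3]),
                 "endloop", "endfacet")
      }
      writeLines(c(out, "endsolid crownmap"), path)
    }
  } else stopf("unsupported mesh format: .%s", ext)
  invisible(path)
}

#' Read a crown annotation sidecar
#'
#' The sidecar is a JSON object with `outline_indices` (1-based ordered
#' vertex indices of the cervical line) and optionally `buccal_anchor`
#' (a 3D point marking the buccal direction), `specimen_id` and `group`.
#'
#' @param path JSON annotation file.
#' @return a list with those fields.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ann$outline_indices))
    stopf("annotation %s lacks outline_indices", path)
  ann$outline_indices <- as.integer(ann$outline_indices)
  if (!is.null(ann$buccal_anchor)) ann$buccal_anchor <- as.numeric(ann$buccal_anchor)
  ann
}

#' Load a crown mesh with its cervical outline
#'
#' @param path mesh file (PLY/OBJ/STL).
#' @param outline ordered 1-based vertex indices of the cervical line, a
#'   path to a JSON annotation sidecar, or `NULL` to use `<path>.json`.
#' @return list with `mesh` (a [tri_mesh()]), `outline` (ordered 3D points,
#'   closure implied), and `buccal_anchor` (3D point or `NULL`).
#' @export
load_mesh <- function(path, outline = NULL) {
  mesh <- read_mesh(path)
  anchor <- NULL
  if (is.null(outline)) outline <- paste0(path, ".json")
  if (is.character(outline)) {
    ann <- read_annotation(outline)
    idx <- ann$outline_indices
    anchor <- ann$buccal_anchor
  } else {
    idx <- as.integer(outline)
  }
  if (length(idx) < 3L) stopf("cervical outline needs at least 3 points")
  if (min(idx) < 1L || max(idx) > nrow(mesh$vertices))
    stopf("outline indices out of range")
  pts <- mesh$vertices[idx, , drop = FALSE]
  list(mesh = mesh, outline = pts, buccal_anchor = anchor)
}
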