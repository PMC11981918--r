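#' Triangulated surface meshes
#'
#' A `surface_mesh` is a minimal triangle-mesh container used throughout the
#' package: a numeric vertex matrix in nanometres and an integer face matrix
#' (1-based vertex indices, counter-clockwise seen from outside so that face
#' normals point outward).
#'
#' @param vertices numeric matrix with three columns (x, y, z in nm).
#' @param faces integer matrix with three columns of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_matrix_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Mesh surface area, enclosed volume and centroid
#'
#' Area is the sum of triangle areas; volume is the signed divergence-theorem
#' volume (positive for outward-oriented closed meshes); the centroid is the
#' area-weighted centroid of the surface.
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_area()` and `mesh_volume()` return a scalar in nm^2 / nm^3;
#'   `mesh_centroid()` returns a length-3 vector in nm.
#' @export
mesh_area <- function(mesh) sum(face_matrix_areas(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

#' @rdname mesh_area
#' @export
mesh_centroid <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  w <- face_matrix_areas(v, f)
  colSums(fc * w) / sum(w)
}

face_centroids <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
      v[f[, 3], , drop = FALSE]) / 3
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

# flip orientation if the signed volume is negative (closed meshes only)
orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

#' Keep the largest connected component of a mesh
#'
#' Components are defined by shared vertices; unreferenced vertices are
#' dropped and faces reindexed.
#'
#' @param mesh a [surface_mesh()].
#' @return A `surface_mesh` containing only the component with the largest
#'   total face area.
#' @export
largest_component <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(mesh)
  comp <- .cpp_face_components(mesh$faces, nrow(mesh$vertices))
  areas <- tapply(face_matrix_areas(mesh$vertices, mesh$faces), comp, sum)
  keep <- comp == as.integer(names(areas)[which.max(areas)])
  subset_faces(mesh, keep)
}

# restrict a mesh to a logical/integer subset of faces, reindexing vertices
subset_faces <- function(mesh, face_sel) {
  f <- mesh$faces[face_sel, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3))
}

#' Sample points uniformly on a mesh surface
#'
#' Faces are drawn proportionally to area, then points uniformly by barycentric
#' coordinates. Deterministic for a fixed seed and input mesh.
#'
#' @param mesh a [surface_mesh()].
#' @param n number of points.
#' @param seed integer seed.
#' @return An `n` x 3 matrix of points (nm).
#' @export
sample_surface_points <- function(mesh, n, seed = 1L) {
  w <- face_matrix_areas(mesh$vertices, mesh$faces)
  if (sum(w) <= 0) stop("degenerate mesh: zero surface area")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = w)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    f <- mesh$faces[idx, , drop = FALSE]
    a <- mesh$vertices[f[, 1], , drop = FALSE]
    b <- mesh$vertices[f[, 2], , drop = FALSE]
    c_ <- mesh$vertices[f[, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
  })
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere; the workhorse
#' parameterization for nucleus and soma phantoms.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   bare icosahedron, each level quadruples the face count).
#' @return A `surface_mesh` with unit-radius vertices.
#' @export
icosphere <- function(subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    nv <- nrow(v)
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- (verts[a, ] + verts[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        edge_mid[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  orient_outward(surface_mesh(v, f))
}

# one-ring vertex adjacency as an index list
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], e[, 1])
}

#' Read and write ASCII PLY meshes
#'
#' Plain-text PLY with vertex x/y/z and triangular faces, the interchange
#' format used for phantom and extracted meshes.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `write_ply()` returns `path` invisibly; `read_ply()` returns a
#'   `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  header_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vl <- lines[header_end + seq_len(nv)]
  fl <- lines[header_end + nv + seq_len(nf)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
  fparts <- matrix(as.integer(unlist(strsplit(fl, " "))), ncol = 4, byrow = TRUE)
  surface_mesh(v, fparts[, 2:4] + 1L)
}
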