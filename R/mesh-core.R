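# Triangle-mesh primitives shared by every module: a mesh is a vertex matrix
# plus a triangle index matrix, always in mm, always 1-based indices.

#' Construct a triangle mesh
#'
#' The elementary geometry container used throughout the package: an `n x 3`
#' numeric matrix of vertex coordinates (mm) and an `m x 3` integer matrix of
#' 1-based triangle indices. Triangle winding is counter-clockwise seen from
#' outside; all generators and readers preserve it.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh must have at least one triangle")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinate")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return 2 x 3 matrix, rows `min` and `max`.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param rotation 3 x 3 rotation matrix (proper orthonormal).
#' @param translation length-3 offset in mm.
#' @param center point about which the rotation is applied (default origin).
#' @return Transformed `tri_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2L, center)
  v <- v %*% t(rotation)
  v <- sweep(v, 2L, center + translation, `+`)
  tri_mesh(v, mesh$faces)
}

apply_rigid <- function(points, rotation, translation, center = c(0, 0, 0)) {
  p <- sweep(rbind(points), 2L, center)
  p <- p %*% t(rotation)
  sweep(p, 2L, center + translation, `+`)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues construction; the axis is normalised internally.
#'
#' @param axis length-3 direction.
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# per-face unit normals (counter-clockwise winding => outward)
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

# Merge several meshes into one (for whole-vertebra queries / export).
merge_meshes <- function(meshes) {
  offs <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs))
}
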