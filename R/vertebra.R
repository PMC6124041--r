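# The per-vertebra container: labelled part meshes, anatomical landmarks and
# a local orthonormal frame (anterior, left-lateral, dorsal).

#' Controlled vocabulary of anatomical part names
#'
#' Part names accepted on a vertebra: the centrum (always required), the
#' neural spine, paired pre-/postzygapophyses and paired cervical ribs.
#'
#' @export
PART_VOCABULARY <- c(
  "centrum", "neural_spine",
  "prezygapophysis_L", "prezygapophysis_R",
  "postzygapophysis_L", "postzygapophysis_R",
  "cervical_rib_L", "cervical_rib_R"
)

#' Construct a labelled vertebra
#'
#' Bundles the part meshes of one vertebra with its anatomical landmarks
#' (anterior-face centroid, posterior-face centroid, dorsal reference point)
#' and local frame. Landmarks omitted by the caller are estimated from the
#' centrum geometry: the anterior/posterior face centroids are the
#' area-weighted centroids of centrum triangles whose outward normals lie
#' within 45 degrees of the +/- anterior axis, and the dorsal reference is the
#' highest centrum vertex along the dorsal axis.
#'
#' @param id vertebra label, e.g. `"C3"`.
#' @param parts named list of [tri_mesh()] objects; names from
#'   [PART_VOCABULARY]; must include `"centrum"`.
#' @param landmarks optional list with elements `anterior`, `posterior`,
#'   `dorsal` (length-3 points, mm); missing elements are estimated.
#' @param frame 3 x 3 matrix whose columns are the unit anterior,
#'   left-lateral and dorsal axes (must be orthonormal within 1e-9).
#' @return An object of class `vertebra_mesh`.
#' @export
vertebra_mesh <- function(id, parts, landmarks = NULL, frame = diag(3)) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  if (is.null(names(parts)) || any(!nzchar(names(parts))))
    stop("parts must be a named list")
  unknown <- setdiff(names(parts), PART_VOCABULARY)
  if (length(unknown))
    stop("unknown part name(s): ", paste(unknown, collapse = ", "),
         " (vocabulary error)")
  if (anyDuplicated(names(parts)))
    stop("duplicate part names")
  if (!"centrum" %in% names(parts))
    stop("'centrum' part is required")
  for (nm in names(parts)) {
    if (!is_tri_mesh(parts[[nm]]))
      stop("part '", nm, "' is not a tri_mesh")
  }
  frame <- as.matrix(frame)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal within 1e-9")
  lm <- estimate_landmarks(parts$centrum, frame)
  if (!is.null(landmarks)) {
    for (nm in intersect(names(landmarks), c("anterior", "posterior", "dorsal")))
      lm[[nm]] <- as.numeric(landmarks[[nm]])
  }
  if (sqrt(sum((lm$anterior - lm$posterior)^2)) <= 1e-12)
    stop("anterior and posterior face centroids coincide")
  structure(
    list(id = id, parts = parts, landmarks = lm, frame = frame),
    class = "vertebra_mesh"
  )
}

#' @export
print.vertebra_mesh <- function(x, ...) {
  ntri <- vapply(x$parts, function(p) nrow(p$faces), integer(1))
  cat(sprintf("<vertebra '%s': %d part(s), %d triangles>\n",
              x$id, length(x$parts), sum(ntri)))
  cat("  parts:", paste(names(x$parts), collapse = ", "), "\n")
  invisible(x)
}

is_vertebra <- function(x) inherits(x, "vertebra_mesh")

# Area-weighted face-centroid landmark estimation on the centrum.
estimate_landmarks <- function(centrum, frame) {
  ant_axis <- frame[, 1L]
  dor_axis <- frame[, 3L]
  n <- face_normals(centrum)
  a <- face_areas(centrum)
  cen <- face_centroids(centrum)
  cos45 <- cos(45 * pi / 180)
  face_centroid <- function(axis) {
    keep <- drop(n %*% axis) >= cos45
    if (!any(keep)) { # fall back to extreme vertex along the axis
      proj <- drop(centrum$vertices %*% axis)
      return(centrum$vertices[which.max(proj), ])
    }
    w <- a[keep]
    colSums(cen[keep, , drop = FALSE] * w) / sum(w)
  }
  proj_d <- drop(centrum$vertices %*% dor_axis)
  list(
    anterior  = face_centroid(ant_axis),
    posterior = face_centroid(-ant_axis),
    dorsal    = centrum$vertices[which.max(proj_d), ]
  )
}

# A rigidly transformed copy of a vertebra (parts, landmarks and frame move
# together).
transform_vertebra <- function(v, rotation = diag(3), translation = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  v$parts <- lapply(v$parts, transform_mesh, rotation = rotation,
                    translation = translation, center = center)
  v$landmarks <- lapply(v$landmarks, function(p)
    drop(apply_rigid(p, rotation, translation, center)))
  v$frame <- rotation %*% v$frame
  v
}
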