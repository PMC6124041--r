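# Articulated-chain posing: neutral pose at preserved or minimum spacing,
# pivot placement between the centra, spacing reduction to centrum contact,
# and rigid per-joint rotations in the three mobility profiles.
#
# World convention follows the local one (+x anterior, +y left, +z dorsal);
# the chain axis is the x axis and the column extends towards -x from the
# first (most anterior) vertebra.

MOBILITY_PROFILES <- c("lateral", "dorsal", "ventral")

#' Joint frame between two consecutive vertebrae
#'
#' The pivot is the midpoint of the segment joining the anterior vertebra's
#' posterior-face centroid and the posterior vertebra's anterior-face
#' centroid, operationalising a point of rotation at the centre of the
#' intervertebral disc. The lateral-flexion axis is the dorsal direction
#' (rotation in the frontal plane); the dorsoventral-flexion axis is the
#' left-lateral direction (rotation in the median plane).
#'
#' @param index joint index (between vertebra `index` and `index + 1`).
#' @param pivot rotation point (mm, world coordinates).
#' @param axis_lateral unit axis of lateral flexion (dorsal direction).
#' @param axis_dorsoventral unit axis of dorsoventral flexion (left-lateral
#'   direction).
#' @param gap current inter-centrum spacing (mm).
#' @return A `joint_frame`.
#' @export
joint_frame <- function(index, pivot, axis_lateral, axis_dorsoventral, gap) {
  u <- axis_lateral / sqrt(sum(axis_lateral^2))
  v <- axis_dorsoventral / sqrt(sum(axis_dorsoventral^2))
  if (abs(sum(u * v)) > 1e-9) stop("joint axes must be orthogonal within 1e-9")
  structure(list(index = as.integer(index), pivot = as.numeric(pivot),
                 axis_lateral = u, axis_dorsoventral = v, gap = gap),
            class = "joint_frame")
}

#' Neutral pose of a column
#'
#' Places every vertebra unrotated with all local anterior axes collinear
#' with the global chain axis, facing landmarks separated by the column's
#' neutral gaps (`preserved` mode), or with the spacing subsequently reduced
#' to centrum contact (`minimum` mode, see [reduce_spacing()]). All applied
#' joint angles are zero.
#'
#' @param column a `vertebra_column` (from [load_column()], [make_column()],
#'   [make_sphere_pair()], ...).
#' @param mode `"preserved"` or `"minimum"` intervertebral spacing.
#' @param epsilon_mm contact tolerance handed to [reduce_spacing()] when
#'   `mode = "minimum"`.
#' @return A `column_pose`.
#' @export
neutral_pose <- function(column, mode = c("preserved", "minimum"),
                         epsilon_mm = 0.01) {
  mode <- match.arg(mode)
  vs <- column$vertebrae
  n <- length(vs)
  if (n < 2L) stop("need at least 2 vertebrae (pose error)")
  gaps <- column$gaps %||% rep(0, n - 1L)
  transforms <- vector("list", n)
  transforms[[1L]] <- list(R = diag(3), t = c(0, 0, 0))
  for (i in seq_len(n - 1L)) {
    a <- vs[[i + 1L]]$landmarks$anterior
    p <- vs[[i]]$landmarks$posterior
    if (sqrt(sum((vs[[i]]$landmarks$anterior - p)^2)) <= 1e-12)
      stop("degenerate frame on vertebra ", vs[[i]]$id, " (pose error)")
    p_world <- p + transforms[[i]]$t
    transforms[[i + 1L]] <- list(R = diag(3),
                                 t = p_world - c(gaps[i], 0, 0) - a)
  }
  pose <- structure(
    list(column = column, mode = "preserved", transforms = transforms,
         joints = NULL,
         angles = matrix(0, n - 1L, 3L,
                         dimnames = list(NULL, MOBILITY_PROFILES)),
         reduction = rep(0, n - 1L)),
    class = "column_pose")
  pose$joints <- compute_all_joints(pose)
  if (mode == "minimum") pose <- reduce_spacing(pose, epsilon_mm)
  pose
}

#' @export
print.column_pose <- function(x, ...) {
  cat(sprintf("<column_pose: %d vertebrae, %s spacing, total applied |angle| %.3g deg>\n",
              length(x$transforms), x$mode, sum(abs(x$angles))))
  invisible(x)
}

# Vertebra i transformed into world coordinates under the pose.
posed_vertebra <- function(pose, i) {
  tr <- pose$transforms[[i]]
  transform_vertebra(pose$column$vertebrae[[i]], tr$R, tr$t)
}

world_landmark <- function(pose, i, which) {
  tr <- pose$transforms[[i]]
  drop(tr$R %*% pose$column$vertebrae[[i]]$landmarks[[which]]) + tr$t
}

#' Compute the joint frame between two consecutive posed vertebrae
#'
#' @param pose a `column_pose`.
#' @param index joint index (anterior vertebra of the pair).
#' @return A [joint_frame()].
#' @export
compute_pivot <- function(pose, index) {
  n <- length(pose$transforms)
  if (index < 1L || index >= n) stop("joint index out of range (parameter error)")
  vA <- pose$column$vertebrae[[index]]
  if (is.null(vA$landmarks$posterior) ||
      is.null(pose$column$vertebrae[[index + 1L]]$landmarks$anterior))
    stop("missing landmarks (landmark error)")
  p <- world_landmark(pose, index, "posterior")
  a <- world_landmark(pose, index + 1L, "anterior")
  RA <- pose$transforms[[index]]$R
  joint_frame(index,
              pivot = (p + a) / 2,
              axis_lateral = drop(RA %*% vA$frame[, 3L]),       # dorsal dir
              axis_dorsoventral = drop(RA %*% vA$frame[, 2L]),  # left dir
              gap = sqrt(sum((p - a)^2)))
}

compute_all_joints <- function(pose) {
  lapply(seq_len(length(pose$transforms) - 1L), function(i) compute_pivot(pose, i))
}

#' Reduce intervertebral spacing to centrum contact
#'
#' Translates each posterior vertebra (and everything behind it) along the
#' chain axis towards its anterior neighbour until the centrum-centrum
#' surface distance lies in `[0, epsilon_mm]`, without interpenetration.
#' Joint frames are recomputed at the collapsed-gap midpoints and the applied
#' translations are recorded so the preserved pose can be recovered.
#'
#' @param pose a neutral preserved-spacing `column_pose`.
#' @param epsilon_mm contact tolerance (mm).
#' @return The pose with `mode = "minimum"`.
#' @export
reduce_spacing <- function(pose, epsilon_mm = 0.01) {
  if (pose$mode != "preserved" || any(pose$angles != 0))
    stop("reduce_spacing requires a neutral preserved-spacing pose")
  n <- length(pose$transforms)
  reduction <- rep(0, n - 1L)
  for (i in seq_len(n - 1L)) {
    cA <- posed_vertebra(pose, i)$parts$centrum
    cB0 <- posed_vertebra(pose, i + 1L)$parts$centrum
    dist_at <- function(t) {
      cB <- tri_mesh(sweep(cB0$vertices, 2L, c(t, 0, 0), `+`), cB0$faces)
      mesh_distance(cA, cB)$distance
    }
    d0 <- dist_at(0)
    if (d0 > epsilon_mm) {
      gap <- pose$joints[[i]]$gap
      hi <- gap + epsilon_mm
      if (dist_at(hi) - epsilon_mm / 2 > 0)
        stop("spacing reduction did not converge at joint ", i,
             " (reduction error)")
      t_star <- stats::uniroot(function(t) dist_at(t) - epsilon_mm / 2,
                               c(0, hi), tol = min(epsilon_mm / 8, 1e-5))$root
      reduction[i] <- t_star
      for (k in (i + 1L):n)
        pose$transforms[[k]]$t <- pose$transforms[[k]]$t + c(t_star, 0, 0)
    }
  }
  pose$reduction <- reduction
  pose$mode <- "minimum"
  pose$joints <- compute_all_joints(pose)
  pose
}

#' Re-expand a reduced pose by its recorded translations
#'
#' Inverse of [reduce_spacing()]: restores the preserved-spacing neutral pose.
#'
#' @param pose a `column_pose` with `mode = "minimum"`.
#' @return The preserved-spacing pose.
#' @export
expand_spacing <- function(pose) {
  if (pose$mode != "minimum") stop("pose is not in minimum-spacing mode")
  n <- length(pose$transforms)
  for (i in seq_len(n - 1L)) {
    if (pose$reduction[i] == 0) next
    for (k in (i + 1L):n)
      pose$transforms[[k]]$t <- pose$transforms[[k]]$t - c(pose$reduction[i], 0, 0)
  }
  pose$reduction <- rep(0, n - 1L)
  pose$mode <- "preserved"
  pose$joints <- compute_all_joints(pose)
  pose
}

profile_axis_sign <- function(joint, profile) {
  switch(profile,
         lateral       = list(axis = joint$axis_lateral, sign = 1),
         lateral_right = list(axis = joint$axis_lateral, sign = 1),
         lateral_left  = list(axis = joint$axis_lateral, sign = -1),
         dorsal        = list(axis = joint$axis_dorsoventral, sign = 1),
         ventral       = list(axis = joint$axis_dorsoventral, sign = -1),
         stop("unknown profile '", profile, "' (parameter error)"))
}

#' Apply a rigid joint rotation
#'
#' Rotates the posterior vertebra of a joint (and, in whole-chain mode, all
#' vertebrae behind it) about the joint pivot around the profile's axis.
#' Sign convention: `dorsal` is positive median-plane rotation, `ventral`
#' negative, `lateral` bends towards the right side (`lateral_left` is
#' provided for symmetry checks). The joint pivot is the one fixed when the
#' pose was created (neutral or post-reduction), matching a protocol in which
#' the point of rotation is set once per manipulation.
#'
#' @param pose a `column_pose`.
#' @param joint joint index.
#' @param profile one of `"lateral"`, `"dorsal"`, `"ventral"`
#'   (or `"lateral_left"`/`"lateral_right"`).
#' @param angle_deg rotation magnitude in degrees, |angle| <= 180.
#' @param chain if `TRUE`, propagate the rotation to all vertebrae posterior
#'   to the joint (whole-chain visualisation mode); default rotates only the
#'   joint's posterior vertebra, replicating two-at-a-time manipulation.
#' @return The updated `column_pose`.
#' @export
apply_rotation <- function(pose, joint, profile, angle_deg, chain = FALSE) {
  n <- length(pose$transforms)
  if (joint < 1L || joint >= n) stop("unknown joint (parameter error)")
  if (abs(angle_deg) > 180) stop("|angle| must be <= 180 (parameter error)")
  jf <- pose$joints[[joint]]
  ax <- profile_axis_sign(jf, profile)
  R <- rotation_about(ax$axis, ax$sign * angle_deg)
  targets <- if (chain) (joint + 1L):n else joint + 1L
  for (k in targets) {
    tr <- pose$transforms[[k]]
    pose$transforms[[k]] <- list(
      R = R %*% tr$R,
      t = drop(R %*% (tr$t - jf$pivot)) + jf$pivot)
  }
  col <- if (profile %in% c("lateral", "lateral_right", "lateral_left"))
    "lateral" else if (profile == "dorsal") "dorsal" else "ventral"
  sgn <- if (profile == "lateral_left") -1 else 1
  pose$angles[joint, col] <- pose$angles[joint, col] + sgn * angle_deg
  pose
}

#' Serialise a pose to JSON
#'
#' Writes per-vertebra homogeneous 4 x 4 transforms plus joint metadata
#' (pivot, axes, gap, spacing mode, applied angles).
#'
#' @param pose a `column_pose`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(pose, path) {
  tf <- lapply(seq_along(pose$transforms), function(i) {
    tr <- pose$transforms[[i]]
    M <- rbind(cbind(tr$R, tr$t), c(0, 0, 0, 1))
    list(id = pose$column$vertebrae[[i]]$id, matrix = M)
  })
  joints <- lapply(pose$joints, function(j)
    list(index = j$index, pivot = j$pivot, axis_lateral = j$axis_lateral,
         axis_dorsoventral = j$axis_dorsoventral, gap = j$gap))
  jsonlite::write_json(
    list(mode = pose$mode, transforms = tf, joints = joints,
         angles_deg = as.data.frame(pose$angles),
         reduction_mm = pose$reduction),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialised pose
#'
#' @param path JSON path written by [write_pose_json()].
#' @return A list with elements `mode`, `transforms` (list of `R`, `t`),
#'   `joints`, `angles_deg`, `reduction_mm`.
#' @export
read_pose_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- lapply(seq_along(x$transforms$id), function(i) {
    M <- x$transforms$matrix[[i]]
    list(id = x$transforms$id[[i]], R = M[1:3, 1:3], t = M[1:3, 4L])
  })
  list(mode = x$mode, transforms = tf, joints = x$joints,
       angles_deg = x$angles_deg, reduction_mm = x$reduction_mm)
}
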