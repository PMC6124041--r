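# Contact detection and the collision-terminated maximal-displacement search;
# runs the preserved-spacing (PCVM) and minimum-spacing (MISM) trials and the
# virtual line-fitting angle measurement.

#' Minimum surface distance between two meshes
#'
#' Exact triangle-to-triangle minimum distance with closest-point witnesses;
#' intersecting surfaces report distance 0.
#'
#' @param a,b [tri_mesh()] objects.
#' @param stop_below optional early-exit threshold: once the running minimum
#'   falls at or below it the scan stops (useful for contact yes/no queries).
#' @return list with `distance` (mm), `point_a`, `point_b`.
#' @export
mesh_distance <- function(a, b, stop_below = -1) {
  cpp_mesh_distance(a$vertices, a$faces, b$vertices, b$faces, stop_below)
}

#' Contact rule: which part pairs terminate motion
#'
#' Bone-on-bone contact is declared when the minimum surface distance between
#' an included part pair falls at or below the tolerance `epsilon_mm`.
#' Excluded pairs never terminate the search (used in the minimum-spacing
#' trial, where the centra start in contact); their interpenetration is
#' allowed but capped and reported.
#'
#' @param include `"all"` (wildcard) or a list of unordered part-name pairs
#'   (length-2 character vectors).
#' @param exclude list of unordered part-name pairs never allowed to stop the
#'   search.
#' @param epsilon_mm contact tolerance (> 0); default 0.1 mm.
#' @param interpenetration_cap_mm maximum tolerated overlap of excluded pairs
#'   before the entry is annotated (mm).
#' @return A `contact_rule`.
#' @export
contact_rule <- function(include = "all", exclude = list(), epsilon_mm = 0.1,
                         interpenetration_cap_mm = 1) {
  if (!(identical(include, "all") || is.list(include)))
    stop("include must be \"all\" or a list of part pairs (rule error)")
  if (epsilon_mm <= 0) stop("epsilon_mm must be > 0 (rule error)")
  norm_pair <- function(p) sort(as.character(p))
  structure(list(
    include = if (identical(include, "all")) "all" else lapply(include, norm_pair),
    exclude = lapply(exclude, norm_pair),
    epsilon_mm = epsilon_mm,
    interpenetration_cap_mm = interpenetration_cap_mm
  ), class = "contact_rule")
}

rule_pair_included <- function(rule, pa, pb) {
  key <- sort(c(pa, pb))
  for (ex in rule$exclude) if (identical(ex, key)) return(FALSE)
  if (identical(rule$include, "all")) return(TRUE)
  for (inc in rule$include) if (identical(inc, key)) return(TRUE)
  FALSE
}

# All included (partA, partB) combinations between two vertebrae.
included_pairs <- function(rule, vA, vB) {
  out <- list()
  for (pa in names(vA$parts)) for (pb in names(vB$parts))
    if (rule_pair_included(rule, pa, pb))
      out[[length(out) + 1L]] <- c(pa, pb)
  out
}

#' Contact query between two posed vertebrae
#'
#' Minimum inter-surface distance over the contact rule's included part pairs
#' only; deterministic for fixed inputs.
#'
#' @param vA,vB posed [vertebra_mesh()] objects (world coordinates).
#' @param rule a [contact_rule()].
#' @param stop_below optional early-exit threshold passed to the distance
#'   query (the reported minimum is then only guaranteed to be at or below
#'   it).
#' @return A `contact_report`: `in_contact`, `distance`, `pair`,
#'   `point_a`, `point_b`.
#' @export
check_contact <- function(vA, vB, rule = contact_rule(), stop_below = -1) {
  pairs <- included_pairs(rule, vA, vB)
  if (!length(pairs)) stop("empty included part-pair set (rule error)")
  best <- list(distance = Inf, pair = c(NA_character_, NA_character_),
               point_a = rep(NA_real_, 3), point_b = rep(NA_real_, 3))
  for (pr in pairs) {
    ma <- vA$parts[[pr[1L]]]; mb <- vB$parts[[pr[2L]]]
    # whole-part AABB lower bound against the running minimum
    ba <- mesh_bbox(ma); bb <- mesh_bbox(mb)
    gap <- pmax(0, pmax(ba[1L, ] - bb[2L, ], bb[1L, ] - ba[2L, ]))
    if (sqrt(sum(gap^2)) >= best$distance) next
    d <- mesh_distance(ma, mb, stop_below = stop_below)
    if (d$distance < best$distance) {
      best <- list(distance = d$distance, pair = pr,
                   point_a = d$point_a, point_b = d$point_b)
      if (best$distance <= stop_below) break
    }
  }
  structure(list(in_contact = best$distance <= rule$epsilon_mm,
                 distance = best$distance, pair = best$pair,
                 point_a = best$point_a, point_b = best$point_b),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report: %s, min distance %.4g mm (%s vs %s)>\n",
              if (x$in_contact) "IN CONTACT" else "clear",
              x$distance, x$pair[1L], x$pair[2L]))
  invisible(x)
}

# Contact state of joint `joint` when its posterior vertebra is rotated by
# `angle` in `profile`, anterior vertebra fixed (pairwise protocol).
joint_contact_at <- function(pose, joint, profile, angle, rule, vA, vB0, jf,
                             fast = TRUE) {
  ax <- profile_axis_sign(jf, profile)
  R <- rotation_about(ax$axis, ax$sign * angle)
  vB <- transform_vertebra(vB0, R, center = jf$pivot)
  check_contact(vA, vB, rule,
                stop_below = if (fast) rule$epsilon_mm else -1)
}

#' Collision-terminated maximal displacement of one joint
#'
#' Finds the largest rotation angle of the joint's posterior vertebra with no
#' included-pair bone-on-bone contact, by a coarse 1-degree forward sweep
#' (taking the first contact, which guards against non-monotone contact)
#' followed by bisection to `tol_deg`. If contact already exists at 0 degrees
#' the result is 0; if no contact occurs up to `bracket_deg`, the bracket is
#' returned with the `limit` flag set.
#'
#' @param pose a `column_pose` (neutral or reduced).
#' @param joint joint index.
#' @param profile `"lateral"`, `"dorsal"`, `"ventral"` (or
#'   `"lateral_left"`).
#' @param rule a [contact_rule()].
#' @param tol_deg bisection tolerance in degrees (> 0), default 0.01.
#' @param bracket_deg search bracket upper bound, default 90.
#' @param sweep_deg coarse pre-sweep step, default 1.
#' @return list with `angle_deg`, `limit` (logical), and `report` (the
#'   first-contact [check_contact()] report at `angle_deg + tol_deg`, or the
#'   bracket/start report).
#' @export
max_displacement <- function(pose, joint, profile, rule = contact_rule(),
                             tol_deg = 0.01, bracket_deg = 90, sweep_deg = 1) {
  if (tol_deg <= 0) stop("tol_deg must be > 0 (parameter error)")
  vA <- posed_vertebra(pose, joint)
  vB0 <- posed_vertebra(pose, joint + 1L)
  jf <- pose$joints[[joint]]
  at <- function(a, fast = TRUE)
    joint_contact_at(pose, joint, profile, a, rule, vA, vB0, jf, fast)
  r0 <- at(0, fast = FALSE)
  if (r0$in_contact)
    return(list(angle_deg = 0, limit = FALSE, report = r0))
  # coarse forward sweep to the first contact
  hit <- NULL
  a_prev <- 0
  a <- sweep_deg
  while (a <= bracket_deg + 1e-12) {
    r <- at(a)
    if (r$in_contact) { hit <- a; break }
    a_prev <- a
    a <- a + sweep_deg
  }
  if (is.null(hit)) {
    rb <- at(bracket_deg, fast = FALSE)
    return(list(angle_deg = bracket_deg, limit = TRUE, report = rb))
  }
  lo <- a_prev; hi <- hit
  while (hi - lo > tol_deg) {
    mid <- (lo + hi) / 2
    if (at(mid)$in_contact) hi <- mid else lo <- mid
  }
  list(angle_deg = lo, limit = FALSE, report = at(hi, fast = FALSE))
}

#' Run a full mobility trial over a column
#'
#' For every consecutive vertebra pair, finds the three per-profile maximal
#' angles. `PCVM` uses the preserved intervertebral spacing and the full
#' contact rule (osteological maximum); `MISM` first reduces the spacing to
#' centrum contact and then excludes centrum-centrum pairs from the rule
#' (osteological minimum). Joints touching damage-masked vertebrae are
#' computed but flagged; joints with no queryable included part pair are
#' marked missing. Geometry errors annotate the affected entry and the trial
#' continues.
#'
#' @param column a `vertebra_column`.
#' @param mode `"PCVM"` or `"MISM"`.
#' @param rule base [contact_rule()].
#' @param tol_deg bisection tolerance (degrees).
#' @param profiles mobility profiles to evaluate.
#' @param reduction_epsilon_mm contact tolerance for the spacing reduction in
#'   `MISM` mode.
#' @param exclude_centra whether `MISM` mode removes centrum-centrum contact
#'   from the stopping rule (default `TRUE`, since those surfaces start in
#'   contact); set `FALSE` to keep the same contact geometry in both spacing
#'   regimes, e.g. on convex single-part fixtures.
#' @return A `rom_table`: data.frame with columns `joint`, `profile`,
#'   `trial`, `angle_deg`, `stop_part_a`, `stop_part_b`, `limit`, `flagged`,
#'   `missing`, `note`.
#' @export
run_trial <- function(column, mode = c("PCVM", "MISM"), rule = contact_rule(),
                      tol_deg = 0.01, profiles = MOBILITY_PROFILES,
                      reduction_epsilon_mm = 0.01,
                      exclude_centra = (mode == "MISM")) {
  mode <- match.arg(mode)
  if (length(column$vertebrae) < 2L) stop("need >= 2 vertebrae")
  if (mode == "PCVM") {
    pose <- neutral_pose(column, "preserved")
  } else {
    pose <- neutral_pose(column, "minimum", epsilon_mm = reduction_epsilon_mm)
    if (exclude_centra)
      rule$exclude <- unique(c(rule$exclude, list(c("centrum", "centrum"))))
  }
  n <- length(column$vertebrae)
  damaged_ids <- names(column$damage)
  rows <- list()
  for (j in seq_len(n - 1L)) {
    idA <- column$vertebrae[[j]]$id
    idB <- column$vertebrae[[j + 1L]]$id
    lbl <- paste0(idA, "-", idB)
    flagged <- any(c(idA, idB) %in% damaged_ids)
    pairs_ok <- length(included_pairs(rule, column$vertebrae[[j]],
                                      column$vertebrae[[j + 1L]])) > 0L
    for (pf in profiles) {
      if (!pairs_ok) {
        # nothing can stop this joint: report the bracket with the limit flag
        rows[[length(rows) + 1L]] <- data.frame(
          joint = lbl, profile = pf, trial = mode, angle_deg = 90,
          stop_part_a = NA_character_, stop_part_b = NA_character_,
          limit = TRUE, flagged = flagged, missing = FALSE,
          note = "no included part pairs", stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(
        max_displacement(pose, j, pf, rule, tol_deg = tol_deg),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          joint = lbl, profile = pf, trial = mode, angle_deg = NA_real_,
          stop_part_a = NA_character_, stop_part_b = NA_character_,
          limit = FALSE, flagged = flagged, missing = TRUE,
          note = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        joint = lbl, profile = pf, trial = mode, angle_deg = res$angle_deg,
        stop_part_a = if (res$limit) NA_character_ else res$report$pair[1L],
        stop_part_b = if (res$limit) NA_character_ else res$report$pair[2L],
        limit = res$limit, flagged = flagged, missing = FALSE, note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rom_table", "data.frame")
  attr(out, "trial") <- mode
  attr(out, "config") <- list(mode = mode, epsilon_mm = rule$epsilon_mm,
                              tol_deg = tol_deg,
                              reduction_epsilon_mm = reduction_epsilon_mm,
                              exclude = rule$exclude)
  out
}

#' @export
print.rom_table <- function(x, ...) {
  cat(sprintf("<rom_table: trial %s, %d entries>\n", attr(x, "trial"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Virtual line-fitting angle measurement
#'
#' Validates the screen-capture measurement protocol against the commanded
#' joint angle: lines are fitted through each vertebra's median-axis
#' landmarks, projected to the median plane (dorsal/ventral profiles) or the
#' frontal plane (lateral profile), and the acute intersection angle is
#' returned. The measurement is repeated `replicates` times, each perturbed
#' by zero-mean Gaussian jitter of sd `jitter_sd_deg` (0 by default, i.e.
#' deterministic), and the replicate mean is returned, mirroring triplicate
#' manual measurement.
#'
#' @param pose a `column_pose` with some applied angle at `joint`.
#' @param joint joint index.
#' @param profile mobility profile the joint was posed in.
#' @param replicates number of repeated measurements.
#' @param jitter_sd_deg measurement-noise standard deviation (degrees).
#' @return Measured angle in degrees (mean over replicates).
#' @export
measure_line_angle <- function(pose, joint, profile, replicates = 3,
                               jitter_sd_deg = 0) {
  if (joint < 1L || joint >= length(pose$transforms))
    stop("unknown joint (state error)")
  dirs <- lapply(c(joint, joint + 1L), function(i) {
    a <- world_landmark(pose, i, "anterior")
    p <- world_landmark(pose, i, "posterior")
    a - p
  })
  keep <- if (profile %in% c("dorsal", "ventral")) c(1L, 3L) else c(1L, 2L)
  ang <- vapply(dirs, function(d) {
    d2 <- d[keep]
    atan2(d2[2L], d2[1L]) * 180 / pi
  }, numeric(1))
  base <- abs(ang[1L] - ang[2L]) %% 360
  if (base > 180) base <- 360 - base
  if (base > 90) base <- 180 - base    # acute intersection angle
  if (jitter_sd_deg > 0) {
    mean(base + stats::rnorm(replicates, 0, jitter_sd_deg))
  } else {
    base
  }
}
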