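# Deterministic parametric vertebra generator. Emulates the qualitative
# cervical morphology relevant to osteologically-stopped motion: amphicoelous
# (double-cupped) centra, a neural spine that can heighten and tilt
# posteriorly along the column, paired overlapping zygapophyseal plates, and
# laterally projecting cervical ribs. Local frame convention: +x anterior,
# +y left, +z dorsal; the centrum axis is the x axis.

# ---- low-level primitive builders -------------------------------------------

# Surface of revolution about the x axis. profile: m x 2 matrix (x, radius),
# radius >= 0; zero-radius endpoints become pole vertices. n = segments per
# revolution. Produces a closed, outward-oriented mesh when the profile runs
# from the +x end to the -x end.
revolve_x <- function(profile, n) {
  m <- nrow(profile)
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  verts <- list(); ring_idx <- vector("list", m); off <- 0L
  for (i in seq_len(m)) {
    r <- profile[i, 2L]
    if (r <= 0) {
      verts[[length(verts) + 1L]] <- matrix(c(profile[i, 1L], 0, 0), 1L)
      ring_idx[[i]] <- off + 1L
      off <- off + 1L
    } else {
      verts[[length(verts) + 1L]] <-
        cbind(profile[i, 1L], r * cos(phi), r * sin(phi))
      ring_idx[[i]] <- off + seq_len(n)
      off <- off + n
    }
  }
  V <- do.call(rbind, verts)
  F <- list()
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(m - 1L)) {
    a <- ring_idx[[i]]; b <- ring_idx[[i + 1L]]
    if (length(a) == 1L && length(b) == n) {        # +x pole fan
      F[[length(F) + 1L]] <- cbind(a, b, b[nxt])
    } else if (length(a) == n && length(b) == 1L) { # -x pole fan
      F[[length(F) + 1L]] <- cbind(b, a[nxt], a)
    } else if (length(a) == n && length(b) == n) {
      F[[length(F) + 1L]] <- cbind(a, b[nxt], a[nxt])
      F[[length(F) + 1L]] <- cbind(a, b, b[nxt])
    }
  }
  tri_mesh(V, do.call(rbind, F))
}

# Axis-aligned box centred at the origin, outward winding.
box_mesh <- function(lx, ly, lz) {
  h <- c(lx, ly, lz) / 2
  V <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1) * h[1],
             c(-1, -1, 1, 1, -1, -1, 1, 1) * h[2],
             c(-1, -1, -1, -1, 1, 1, 1, 1) * h[3])
  F <- rbind(c(1, 4, 3), c(1, 3, 2),  # z-
             c(5, 6, 7), c(5, 7, 8),  # z+
             c(1, 2, 6), c(1, 6, 5),  # y-
             c(3, 4, 8), c(3, 8, 7),  # y+
             c(4, 1, 5), c(4, 5, 8),  # x-
             c(2, 3, 7), c(2, 7, 6))  # x+
  tri_mesh(V, F)
}

# Reflect a mesh across the median (y = 0) plane, restoring outward winding.
mirror_mesh <- function(m) {
  v <- m$vertices
  v[, 2L] <- -v[, 2L]
  tri_mesh(v, m$faces[, c(1L, 3L, 2L), drop = FALSE])
}

# UV sphere of radius r centred at the origin.
sphere_mesh <- function(r, n) {
  psi <- seq(0, pi, length.out = max(4L, floor(n / 2)) + 1L)
  revolve_x(cbind(r * cos(psi), r * sin(psi)), n)
}

# Amphicoelous centrum: capped cylinder along x with concave (cupped) end
# faces of depth d; quadratic cup profile so the face normals stay within the
# landmark-estimation cone.
centrum_mesh <- function(r, L, d, n, n_cup = 4L) {
  t <- seq(0, 1, length.out = n_cup + 1L)     # 0 = cup centre, 1 = rim
  cup_x <- L / 2 - d * (1 - t^2)
  profile <- rbind(
    cbind(cup_x, r * t),                       # anterior cup, centre -> rim
    cbind(-rev(cup_x), r * rev(t))             # barrel + posterior cup
  )
  revolve_x(profile, n)
}

# ---- parameter containers ---------------------------------------------------

#' Parameters of one synthetic vertebra
#'
#' All lengths in mm, angles in degrees. Geometry is fully deterministic for
#' fixed parameters and seed; optional vertex jitter (off by default) is the
#' only stochastic element.
#'
#' @param centrum_radius centrum barrel radius.
#' @param centrum_length centrum length along the anterior axis; the anterior
#'   and posterior face planes sit at +/- `centrum_length / 2`.
#' @param concavity_depth depth of the amphicoelous cup at each centrum face;
#'   must be < `centrum_length / 2`.
#' @param spine_height dorsal extent of the neural spine tip above the centrum
#'   axis (at zero posterior angle).
#' @param spine_posterior_angle posterior tilt of the spine, degrees from the
#'   dorsal axis.
#' @param zygapophysis_angle inclination of the zygapophyseal facet plates
#'   from the horizontal plane, degrees.
#' @param zygapophysis_offset lateral distance of each facet plate centre from
#'   the median plane.
#' @param rib_length lateral projection of each cervical rib beyond the
#'   centrum surface.
#' @param mesh_resolution segments per revolution for curved surfaces (>= 8).
#' @param parts character vector of parts to generate (subset of
#'   [PART_VOCABULARY]).
#' @param jitter_sd standard deviation (mm) of optional Gaussian vertex
#'   jitter; 0 disables it.
#' @param seed integer seed controlling the jitter stream.
#' @return A `vertebra_params` list.
#' @export
vertebra_params <- function(centrum_radius = 10, centrum_length = 20,
                            concavity_depth = 2, spine_height = 20,
                            spine_posterior_angle = 0,
                            zygapophysis_angle = 10, zygapophysis_offset = 6,
                            rib_length = 30, mesh_resolution = 16,
                            parts = PART_VOCABULARY,
                            jitter_sd = 0, seed = 1L) {
  p <- list(centrum_radius = centrum_radius, centrum_length = centrum_length,
            concavity_depth = concavity_depth, spine_height = spine_height,
            spine_posterior_angle = spine_posterior_angle,
            zygapophysis_angle = zygapophysis_angle,
            zygapophysis_offset = zygapophysis_offset,
            rib_length = rib_length, mesh_resolution = as.integer(mesh_resolution),
            parts = parts, jitter_sd = jitter_sd, seed = as.integer(seed))
  lens <- c(p$centrum_radius, p$centrum_length, p$concavity_depth,
            p$spine_height, p$zygapophysis_offset, p$rib_length)
  if (any(!is.finite(lens)) || any(lens < 0))
    stop("all lengths must be finite and >= 0 (parameter error)")
  if (p$concavity_depth >= p$centrum_length / 2)
    stop("concavity_depth must be < centrum_length / 2 (parameter error)")
  if (p$mesh_resolution < 8L)
    stop("mesh_resolution must be >= 8 (parameter error)")
  if (length(setdiff(p$parts, PART_VOCABULARY)))
    stop("unknown part name(s) in 'parts' (parameter error)")
  class(p) <- "vertebra_params"
  p
}

#' Specification of a synthetic vertebral column
#'
#' @param n_vertebrae number of vertebrae (>= 2).
#' @param base a [vertebra_params()] object used for the first vertebra.
#' @param gradients named list of additive per-index deltas applied to
#'   `spine_height`, `spine_posterior_angle`, `zygapophysis_angle` and/or
#'   `rib_length` (vertebra i receives `base + (i - 1) * delta`).
#' @param gap intervertebral gap g (mm): scalar or length `n_vertebrae - 1`.
#' @param damage named list: vertebra id -> character vector of parts removed
#'   (emulating excavation damage).
#' @return A `column_spec` list.
#' @export
column_spec <- function(n_vertebrae = 24L, base = vertebra_params(),
                        gradients = list(), gap = 2, damage = NULL) {
  n_vertebrae <- as.integer(n_vertebrae)
  if (n_vertebrae < 2L) stop("n_vertebrae must be >= 2 (parameter error)")
  if (any(gap < 0)) stop("gap must be >= 0 (parameter error)")
  gaps <- if (length(gap) == 1L) rep(gap, n_vertebrae - 1L) else gap
  if (length(gaps) != n_vertebrae - 1L)
    stop("gap must be scalar or length n_vertebrae - 1")
  allowed <- c("spine_height", "spine_posterior_angle", "zygapophysis_angle",
               "rib_length")
  if (length(setdiff(names(gradients), allowed)))
    stop("gradients allowed only for: ", paste(allowed, collapse = ", "))
  structure(list(n_vertebrae = n_vertebrae, base = base,
                 gradients = gradients, gaps = gaps, damage = damage),
            class = "column_spec")
}

# ---- generators -------------------------------------------------------------

#' Default synthetic study-column conditions
#'
#' The reference 24-vertebra cervical column used throughout the package's
#' examples and validation runs: morphological gradients along the column
#' (heightening, posteriorly tilting neural spines and re-angulating facets),
#' a preserved intervertebral spacing that narrows posteriorly, and an
#' excavation-damage mask removing the neural spines and cervical ribs of
#' C7-C9. The dimensions are documented conventions of the generator, not
#' measurements of any specimen.
#'
#' @param n_vertebrae number of cervical vertebrae (default 24).
#' @return A [column_spec()].
#' @export
default_column_spec <- function(n_vertebrae = 24L) {
  n <- as.integer(n_vertebrae)
  damage <- NULL
  if (n >= 9L) {
    damage <- rep(list(c("neural_spine", "cervical_rib_L", "cervical_rib_R")), 3L)
    names(damage) <- c("C7", "C8", "C9")
  }
  column_spec(
    n_vertebrae = n,
    base = vertebra_params(),
    gradients = list(spine_height = 0.15, spine_posterior_angle = 0.8,
                     zygapophysis_angle = 0.5, rib_length = -0.3),
    gap = seq(2.6, 2.0, length.out = n - 1L),
    damage = damage)
}

#' Generate one labelled synthetic vertebra
#'
#' Produces a bilaterally symmetric vertebra in its local frame (+x anterior,
#' +y left, +z dorsal; centrum axis = x axis) with analytic landmarks: the
#' anterior/posterior face points on the centrum axis at the face planes, and
#' the dorsal reference at the top of the centrum barrel.
#'
#' @param params a [vertebra_params()] object.
#' @param id vertebra label (default `"V1"`).
#' @return A [vertebra_mesh()].
#' @export
make_vertebra <- function(params = vertebra_params(), id = "V1") {
  if (!inherits(params, "vertebra_params")) params <- do.call(vertebra_params, params)
  r <- params$centrum_radius; L <- params$centrum_length
  n <- params$mesh_resolution
  parts <- list()
  parts$centrum <- centrum_mesh(r, L, params$concavity_depth, n)

  if ("neural_spine" %in% params$parts && params$spine_height > 0) {
    h <- params$spine_height
    base_z <- 0.9 * r
    if (h <= base_z)
      stop("spine_height must exceed 0.9 * centrum_radius (parameter error)")
    sp <- box_mesh(0.92 * L, 0.3 * r, h - base_z)
    sp <- transform_mesh(sp, translation = c(0, 0, (h + base_z) / 2))
    # posterior tilt about the spine base point
    sp <- transform_mesh(sp, rotation_about(c(0, 1, 0), -params$spine_posterior_angle),
                         center = c(0, 0, base_z))
    parts$neural_spine <- sp
  }

  zyg_parts <- intersect(c("prezygapophysis_L", "prezygapophysis_R",
                           "postzygapophysis_L", "postzygapophysis_R"),
                         params$parts)
  if (length(zyg_parts)) {
    plate_lx <- 0.4 * L; plate_wy <- 0.5 * r; plate_tz <- 0.1 * r
    clearance <- 0.1 * r     # facet clearance (prezygapophysis below)
    post_z <- r + 0.55 * r   # postzygapophysis plate centre height
    pre_z <- post_z - plate_tz - clearance
    make_plate <- function(cx, cz) {
      pl <- box_mesh(plate_lx, plate_wy, plate_tz)
      # facet inclination from horizontal, tilted about the anterior axis
      pl <- transform_mesh(pl, rotation_about(c(1, 0, 0), -params$zygapophysis_angle))
      transform_mesh(pl, translation = c(cx, -params$zygapophysis_offset, cz))
    }
    pre_R <- make_plate(L / 2 + 0.1 * L, pre_z)    # extends past the anterior face
    post_R <- make_plate(-L / 2 - 0.1 * L, post_z) # extends past the posterior face
    if ("prezygapophysis_R" %in% zyg_parts) parts$prezygapophysis_R <- pre_R
    if ("prezygapophysis_L" %in% zyg_parts) parts$prezygapophysis_L <- mirror_mesh(pre_R)
    if ("postzygapophysis_R" %in% zyg_parts) parts$postzygapophysis_R <- post_R
    if ("postzygapophysis_L" %in% zyg_parts) parts$postzygapophysis_L <- mirror_mesh(post_R)
  }

  rib_parts <- intersect(c("cervical_rib_L", "cervical_rib_R"), params$parts)
  if (length(rib_parts) && params$rib_length > 0) {
    y0 <- 0.8 * r; y1 <- r + params$rib_length
    rib <- box_mesh(0.8 * L, y1 - y0, 0.3 * r)
    v <- rib$vertices
    # taper the dorsoventral thickness towards the lateral tip (x-width kept)
    tip <- v[, 2L] > 0
    v[tip, 3L] <- v[tip, 3L] * 0.3
    v[, 2L] <- -(v[, 2L] + (y0 + y1) / 2)  # right side: negative y
    rib <- tri_mesh(v, rib$faces[, c(1L, 3L, 2L), drop = FALSE]) # mirrored above
    if ("cervical_rib_R" %in% rib_parts) parts$cervical_rib_R <- rib
    if ("cervical_rib_L" %in% rib_parts) parts$cervical_rib_L <- mirror_mesh(rib)
  }

  parts <- parts[intersect(PART_VOCABULARY, names(parts))]
  if (params$jitter_sd > 0) {
    rng <- local_rng(params$seed)
    parts <- lapply(parts, function(m) {
      m$vertices <- m$vertices +
        matrix(rng$rnorm(length(m$vertices), 0, params$jitter_sd),
               ncol = 3L)
      m
    })
  }
  vertebra_mesh(id, parts,
                landmarks = list(anterior = c(L / 2, 0, 0),
                                 posterior = c(-L / 2, 0, 0),
                                 dorsal = c(0, 0, r)))
}

# isolated RNG stream so generation never disturbs the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  }
  env$rnorm <- function(n, mean = 0, sd = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n, mean, sd)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
  env
}

#' Generate a synthetic vertebral column
#'
#' Applies the column specification's per-index morphological gradients (spine
#' heightening, posterior spine tilt, facet re-angulation) and the damage
#' mask, and returns the column with its neutral intervertebral gaps.
#'
#' @param spec a [column_spec()].
#' @return A `vertebra_column` (see [load_column()]): `n_vertebrae` labelled
#'   meshes in anterior-to-posterior order plus `n_vertebrae - 1` neutral
#'   gaps.
#' @export
make_column <- function(spec = column_spec()) {
  if (!inherits(spec, "column_spec")) stop("spec must be a column_spec")
  vertebrae <- vector("list", spec$n_vertebrae)
  for (i in seq_len(spec$n_vertebrae)) {
    p <- spec$base
    for (nm in names(spec$gradients))
      p[[nm]] <- p[[nm]] + (i - 1) * spec$gradients[[nm]]
    id <- sprintf("C%d", i)
    if (!is.null(spec$damage) && id %in% names(spec$damage))
      p$parts <- setdiff(p$parts, spec$damage[[id]])
    class(p) <- "vertebra_params"
    vertebrae[[i]] <- make_vertebra(p, id = id)
  }
  structure(list(vertebrae = vertebrae, gaps = spec$gaps, damage = spec$damage),
            class = "vertebra_column")
}

#' Analytic sphere-pair fixture
#'
#' Two spheres of radius `r` with centres `2 r + g` apart along the chain
#' axis, each wrapped as a single-part (centrum) vertebra with landmarks at
#' the facing surface points. The collision-terminated maximal rotation of
#' this fixture has the closed form `acos(2 r^2 / (r + g/2)^2 - 1)`, making it
#' the package's primary search oracle.
#'
#' @param r sphere radius (mm), > 0.
#' @param g inter-surface gap (mm), >= 0.
#' @param mesh_resolution segments per revolution.
#' @return A 2-vertebra `vertebra_column` with gap `g`.
#' @export
make_sphere_pair <- function(r, g, mesh_resolution = 32L) {
  make_sphere_chain(2L, r, g, mesh_resolution)
}

#' Chain of identical spheres
#'
#' Convex multi-joint fixture generalising [make_sphere_pair()]; used for
#' gap-monotonicity and minimum-vs-preserved spacing properties.
#'
#' @param n number of spheres (>= 2).
#' @param r sphere radius (mm), > 0.
#' @param g gap(s): scalar or length `n - 1`.
#' @param mesh_resolution segments per revolution.
#' @return A `vertebra_column`.
#' @export
make_sphere_chain <- function(n, r, g, mesh_resolution = 32L) {
  if (r <= 0) stop("r must be > 0 (parameter error)")
  if (any(g < 0)) stop("g must be >= 0 (parameter error)")
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2 (parameter error)")
  gaps <- if (length(g) == 1L) rep(g, n - 1L) else g
  if (length(gaps) != n - 1L) stop("g must be scalar or length n - 1")
  sph <- sphere_mesh(r, mesh_resolution)
  vertebrae <- vector("list", n)
  for (i in seq_len(n)) {
    vertebrae[[i]] <- vertebra_mesh(
      sprintf("S%d", i), list(centrum = sph),
      landmarks = list(anterior = c(r, 0, 0), posterior = c(-r, 0, 0),
                       dorsal = c(0, 0, r)))
  }
  structure(list(vertebrae = vertebrae, gaps = gaps, damage = NULL),
            class = "vertebra_column")
}
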