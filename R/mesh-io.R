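# Mesh and table I/O: Wavefront OBJ (required format, with named face groups),
# ASCII PLY and ASCII STL (accepted), JSON column manifests, and the CSV angle
# tables exchanged with the statistics module.

UNIT_SCALE_MM <- c(mm = 1, cm = 10, m = 1000, um = 1e-3)

#' Read a Wavefront OBJ file
#'
#' Supports `v` and `f` records and named `g`/`o` groups; polygonal faces are
#' fan-triangulated. Face records of the form `v/vt/vn` are accepted (only the
#' vertex index is used).
#'
#' @param path file path.
#' @param split_groups if `TRUE`, return a named list of [tri_mesh()] objects,
#'   one per face group; otherwise a single mesh.
#' @return A `tri_mesh`, or a named list of them.
#' @export
read_obj <- function(path, split_groups = FALSE) {
  if (!file.exists(path)) stop("cannot open mesh file: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  verts <- list()
  groups <- list()
  cur <- "default"
  for (tk in toks) {
    if (length(tk) == 0L || tk[1L] == "" || startsWith(tk[1L], "#")) next
    key <- tk[1L]
    if (key == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(tk[2:4])
    } else if (key == "g" || key == "o") {
      cur <- if (length(tk) >= 2L) tk[2L] else "default"
    } else if (key == "f") {
      idx <- as.integer(vapply(tk[-1L],
                               function(s) strsplit(s, "/", fixed = TRUE)[[1L]][1L],
                               character(1)))
      if (length(idx) < 3L) stop("face with fewer than 3 vertices in ", path)
      tris <- cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
      groups[[cur]] <- c(groups[[cur]], list(tris))
    }
  }
  if (!length(verts)) stop("no vertices parsed from ", path)
  V <- do.call(rbind, verts)
  if (!all(is.finite(V))) stop("non-finite vertex coordinate in ", path)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (!length(groups)) stop("no faces parsed from ", path)
  build <- function(fl) {
    F <- do.call(rbind, fl)
    used <- sort(unique(as.vector(F)))
    remap <- integer(nrow(V)); remap[used] <- seq_along(used)
    tri_mesh(V[used, , drop = FALSE],
             matrix(remap[F], ncol = 3L))
  }
  if (split_groups) lapply(groups, build) else build(unlist(groups, recursive = FALSE))
}

#' Write meshes to a Wavefront OBJ file
#'
#' @param mesh a [tri_mesh()] or a named list of them; list names become OBJ
#'   face-group (`g`) names.
#' @param path output path.
#' @param digits significant digits for vertex coordinates (default preserves
#'   mm coordinates well below 1e-6 mm).
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, digits = 12L) {
  meshes <- if (is_tri_mesh(mesh)) list(mesh = mesh) else mesh
  con <- file(path, "w")
  on.exit(close(con))
  offs <- 0L
  fmt <- paste0("v %.", digits, "g %.", digits, "g %.", digits, "g")
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    writeLines(paste0("g ", nm), con)
    writeLines(sprintf(fmt, m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d",
                       m$faces[, 1] + offs, m$faces[, 2] + offs, m$faces[, 3] + offs),
               con)
    offs <- offs + nrow(m$vertices)
  }
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("cannot open mesh file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated in ", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format[[:space:]]+binary", hdr)))
    stop("binary PLY not supported: ", path)
  nv <- as.integer(sub("^element[[:space:]]+vertex[[:space:]]+", "",
                       grep("^element[[:space:]]+vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element[[:space:]]+face[[:space:]]+", "",
                       grep("^element[[:space:]]+face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY missing vertex/face elements: ", path)
  body <- strsplit(trimws(lines[(hdr_end + 1L):length(lines)]), "[[:space:]]+")
  body <- body[vapply(body, function(x) length(x) > 0L && nzchar(x[1L]), logical(1))]
  V <- t(vapply(body[seq_len(nv)], function(x) as.numeric(x[1:3]), numeric(3)))
  F <- lapply(body[nv + seq_len(nf)], function(x) {
    k <- as.integer(x[1L])
    idx <- as.integer(x[2:(1L + k)]) + 1L # PLY is 0-based
    cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
  })
  tri_mesh(V, do.call(rbind, F))
}

#' Read an ASCII STL file
#'
#' Exact-duplicate vertices are welded so the result has a shared vertex set.
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("cannot open mesh file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || !startsWith(lines[1L], "solid"))
    stop("not an ASCII STL file: ", path)
  vl <- grep("^vertex[[:space:]]", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("malformed STL facet list in ", path)
  V <- t(vapply(strsplit(vl, "[[:space:]]+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  key <- apply(V, 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  tri_mesh(V[uk, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

read_mesh_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path),
         stop("unsupported mesh format '", ext, "' for ", path))
}

#' Read a column manifest
#'
#' A manifest is a JSON file declaring the anterior-to-posterior vertebra
#' order, the part meshes of each vertebra (either one file per part, or a
#' single OBJ whose face groups are named by part), measurement units,
#' optional landmark/frame overrides, optional per-joint neutral gaps and an
#' optional damage mask.
#'
#' @param path manifest JSON path.
#' @return The parsed manifest list (paths kept relative; resolved on load).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot open manifest: ", path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(man$units)) stop("manifest must declare units")
  if (!man$units %in% names(UNIT_SCALE_MM))
    stop("unknown units '", man$units, "' (use mm, cm, m or um)")
  ids <- vapply(man$vertebrae, function(v) v$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate vertebra ids in manifest")
  if (!is.null(man$damage)) {
    bad <- setdiff(unlist(lapply(man$damage, `[[`, "id")), ids)
    if (length(bad)) stop("damage mask names unknown vertebra id(s): ",
                          paste(bad, collapse = ", "))
  }
  attr(man, "dir") <- dirname(normalizePath(path))
  man
}

#' Load a vertebral column from a manifest
#'
#' Reads every part mesh, rescales coordinates to mm according to the
#' manifest's units declaration, applies landmark overrides where present and
#' estimates landmarks otherwise. Coordinates are otherwise unchanged.
#'
#' @param manifest a parsed manifest from [read_manifest()], or a path to one.
#' @return A `vertebra_column`: list with `vertebrae` (list of
#'   [vertebra_mesh()] in manifest order), `gaps` (per-joint neutral gaps in
#'   mm, or `NULL`), and `damage` (named list of removed parts per vertebra).
#' @export
load_column <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  base <- attr(manifest, "dir") %||% "."
  scale <- UNIT_SCALE_MM[[manifest$units]]
  scale_mesh <- function(m) if (scale == 1) m else tri_mesh(m$vertices * scale, m$faces)
  vertebrae <- lapply(manifest$vertebrae, function(entry) {
    if (!is.null(entry$file)) { # single file, parts as face groups
      p <- file.path(base, entry$file)
      parts <- read_obj(p, split_groups = TRUE)
    } else if (!is.null(entry$parts)) {
      parts <- lapply(entry$parts, function(f) read_mesh_file(file.path(base, f)))
    } else stop("manifest entry '", entry$id, "' has neither file nor parts")
    parts <- lapply(parts, scale_mesh)
    lms <- if (!is.null(entry$landmarks))
      lapply(entry$landmarks, function(p) unlist(p) * scale)
    frame <- if (!is.null(entry$frame))
      matrix(unlist(entry$frame), 3L, 3L) else diag(3)
    vertebra_mesh(entry$id, parts, landmarks = lms, frame = frame)
  })
  damage <- NULL
  if (!is.null(manifest$damage)) {
    damage <- lapply(manifest$damage, function(d) unlist(d$missing_parts))
    names(damage) <- vapply(manifest$damage, function(d) d$id, character(1))
  }
  gaps <- if (!is.null(manifest$gaps)) unlist(manifest$gaps) * scale
  structure(list(vertebrae = vertebrae, gaps = gaps, damage = damage),
            class = "vertebra_column")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vertebra_column <- function(x, ...) {
  cat(sprintf("<vertebra_column: %d vertebrae (%s)>\n", length(x$vertebrae),
              paste(vapply(x$vertebrae, `[[`, character(1), "id"),
                    collapse = " > ")))
  invisible(x)
}

#' Read an angle table CSV
#'
#' The exchange format for measured intervertebral angles:
#' `joint,profile,trial,angle_deg`. This is the format emitted for ROM tables
#' and accepted by the statistics front end (e.g. for externally measured
#' radiograph angles).
#'
#' @param path CSV path.
#' @return data.frame with those four columns.
#' @export
read_angle_table <- function(path) {
  if (!file.exists(path)) stop("cannot open angle table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("joint", "profile", "trial", "angle_deg")
  if (!all(need %in% names(df)))
    stop("angle table must have columns ", paste(need, collapse = ","))
  df$angle_deg <- as.numeric(df$angle_deg)
  df[need]
}

#' Write an angle table CSV
#'
#' @param df data.frame with columns `joint,profile,trial,angle_deg`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_table <- function(df, path) {
  need <- c("joint", "profile", "trial", "angle_deg")
  if (!all(need %in% names(df)))
    stop("angle table must have columns ", paste(need, collapse = ","))
  utils::write.csv(format_num_df(df[need]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic numeric formatting for byte-stable CSV output.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.15g", df[[j]])
  }
  df
}

#' Persist results tables
#'
#' Writes ROM tables, summary tables and test matrices to CSV (stable,
#' documented columns) or, for `.json` paths, to JSON carrying full
#' configuration provenance when the object has a `config` attribute.
#'
#' @param x a `rom_table`, summary data.frame, or `ww_matrix`.
#' @param path output path; extension selects CSV vs JSON.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.rom_table <- function(x, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    out <- list(trial = attr(x, "trial"),
                config = attr(x, "config"),
                rows = x)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(format_num_df(as.data.frame(x)), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path) {
  utils::write.csv(format_num_df(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.ww_matrix <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(format_num_df(df), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
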