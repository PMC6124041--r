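# Programmatic fixtures: everything is built in code at test time.

# Unit cube as an OBJ file; returns the path.
write_unit_cube_obj <- function(path) {
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v$x, v$y, v$z),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  path
}

# Write a generated column as one OBJ per part plus a manifest; returns the
# manifest path.
write_test_manifest <- function(dir, column, units = "mm", scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(column$vertebrae, function(v) {
    files <- list()
    for (nm in names(v$parts)) {
      f <- paste0(v$id, "_", nm, ".obj")
      m <- v$parts[[nm]]
      write_obj(tri_mesh(m$vertices * scale, m$faces), file.path(dir, f))
      files[[nm]] <- f
    }
    list(id = v$id, parts = files,
         landmarks = lapply(v$landmarks, function(p) p * scale))
  })
  man <- list(units = units, vertebrae = entries,
              gaps = as.list(column$gaps * scale))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

# A small regular tetrahedron in PLY and STL text forms.
tetra_vertices <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
tetra_faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))

write_tetra_ply <- function(path) {
  v <- tetra_vertices; f <- tetra_faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  path
}

write_tetra_stl <- function(path) {
  v <- tetra_vertices; f <- tetra_faces
  lines <- c("solid tetra")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               sprintf("vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid tetra"), path)
  path
}

# Two-vertebra synthetic column without gradients (bilaterally symmetric).
symmetric_pair_column <- function(gap = 2, ...) {
  make_column(column_spec(n_vertebrae = 2, base = vertebra_params(...),
                          gap = gap))
}
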