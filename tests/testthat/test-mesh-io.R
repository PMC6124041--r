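# Mesh and manifest I/O: formats, units, round trips, validation errors.

test_that("a one-part manifest with a unit-cube OBJ loads as a centrum", {
  dir <- withr::local_tempdir()
  write_unit_cube_obj(file.path(dir, "cube.obj"))
  jsonlite::write_json(
    list(units = "mm",
         vertebrae = list(list(id = "C1", parts = list(centrum = "cube.obj")))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  col <- load_column(file.path(dir, "manifest.json"))
  expect_length(col$vertebrae, 1L)
  v <- col$vertebrae[[1L]]
  expect_identical(names(v$parts), "centrum")
  expect_identical(nrow(v$parts$centrum$vertices), 8L)
  expect_identical(nrow(v$parts$centrum$faces), 12L)
})

test_that("generated vertebrae survive a save/reload round trip within 1e-6 mm", {
  dir <- withr::local_tempdir()
  column <- symmetric_pair_column()
  man <- write_test_manifest(dir, column)
  re <- load_column(man)
  for (i in 1:2) {
    orig <- column$vertebrae[[i]]
    back <- re$vertebrae[[i]]
    expect_setequal(names(back$parts), names(orig$parts))
    for (nm in names(orig$parts)) {
      expect_lt(max(abs(back$parts[[nm]]$vertices - orig$parts[[nm]]$vertices)),
                1e-6)
      expect_identical(back$parts[[nm]]$faces, orig$parts[[nm]]$faces)
      # loading never mutates coordinates: bounding boxes match the source
      expect_equal(mesh_bbox(back$parts[[nm]]), mesh_bbox(orig$parts[[nm]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("manifest units are rescaled to mm on load", {
  dir <- withr::local_tempdir()
  column <- symmetric_pair_column()
  man <- write_test_manifest(dir, column, units = "cm", scale = 0.1)
  re <- load_column(man)
  expect_equal(re$vertebrae[[1L]]$parts$centrum$vertices,
               column$vertebrae[[1L]]$parts$centrum$vertices,
               tolerance = 1e-9)
  expect_equal(re$gaps, column$gaps, tolerance = 1e-12)
})

test_that("load errors identify the offending input", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(
    list(units = "mm",
         vertebrae = list(list(id = "C1",
                               parts = list(centrum = "no_such_file.obj")))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_column(file.path(dir, "manifest.json")), "no_such_file.obj")

  write_unit_cube_obj(file.path(dir, "cube.obj"))
  jsonlite::write_json(
    list(units = "mm",
         vertebrae = list(list(id = "C1", parts = list(humerus = "cube.obj")))),
    file.path(dir, "man2.json"), auto_unbox = TRUE)
  expect_error(load_column(file.path(dir, "man2.json")), "humerus")

  jsonlite::write_json(
    list(units = "furlong",
         vertebrae = list(list(id = "C1", parts = list(centrum = "cube.obj")))),
    file.path(dir, "man3.json"), auto_unbox = TRUE)
  expect_error(read_manifest(file.path(dir, "man3.json")), "units")
})

test_that("PLY and STL readers agree with the OBJ reader on the same solid", {
  dir <- withr::local_tempdir()
  ply <- read_ply(write_tetra_ply(file.path(dir, "t.ply")))
  stl <- read_stl(write_tetra_stl(file.path(dir, "t.stl")))
  writeLines(c(sprintf("v %g %g %g", tetra_vertices[, 1], tetra_vertices[, 2],
                       tetra_vertices[, 3]),
               sprintf("f %d %d %d", tetra_faces[, 1], tetra_faces[, 2],
                       tetra_faces[, 3])),
             file.path(dir, "t.obj"))
  obj <- read_obj(file.path(dir, "t.obj"))
  expect_equal(ply$vertices, obj$vertices, tolerance = 1e-12)
  expect_identical(ply$faces, obj$faces)
  # STL welds duplicated facet vertices back to a shared vertex set
  expect_identical(nrow(stl$vertices), 4L)
  expect_identical(nrow(stl$faces), 4L)
  expect_equal(sort(stl$vertices[, 1] + 10 * stl$vertices[, 2] +
                      100 * stl$vertices[, 3]),
               sort(obj$vertices[, 1] + 10 * obj$vertices[, 2] +
                      100 * obj$vertices[, 3]), tolerance = 1e-12)
})

test_that("OBJ face groups split into named parts", {
  dir <- withr::local_tempdir()
  v <- make_vertebra(vertebra_params(parts = c("centrum", "neural_spine")))
  path <- file.path(dir, "v.obj")
  write_obj(v$parts, path)
  parts <- read_obj(path, split_groups = TRUE)
  expect_setequal(names(parts), c("centrum", "neural_spine"))
  expect_equal(parts$neural_spine$vertices, v$parts$neural_spine$vertices,
               tolerance = 1e-9)
})

test_that("angle tables round-trip all numeric fields within 1e-9", {
  dir <- withr::local_tempdir()
  set.seed(7)
  df <- data.frame(joint = sprintf("C%d-C%d", 1:12, 2:13),
                   profile = rep(c("lateral", "dorsal", "ventral"), 4),
                   trial = rep(c("PCVM", "MISM"), each = 6),
                   angle_deg = runif(12, 0, 25))
  p <- file.path(dir, "angles.csv")
  write_angle_table(df, p)
  back <- read_angle_table(p)
  expect_identical(back$joint, df$joint)
  expect_lt(max(abs(back$angle_deg - df$angle_deg)), 1e-9)
})

test_that("ROM tables persist with stable columns, including when empty", {
  dir <- withr::local_tempdir()
  col <- make_sphere_chain(3, 1, 0.3, mesh_resolution = 16)
  tb <- run_trial(col, "PCVM", contact_rule(epsilon_mm = 0.01), tol_deg = 0.1)
  p <- file.path(dir, "rom.csv")
  write_results(tb, p)
  back <- utils::read.csv(p)
  expect_identical(nrow(back), 6L) # 2 joints x 3 profiles
  expect_true(all(c("joint", "profile", "trial", "angle_deg") %in% names(back)))

  empty <- tb[0, ]
  class(empty) <- c("rom_table", "data.frame")
  attr(empty, "trial") <- "PCVM"
  p2 <- file.path(dir, "empty.csv")
  expect_silent(write_results(empty, p2))
  expect_identical(nrow(utils::read.csv(p2)), 0L)

  p3 <- file.path(dir, "rom.json")
  write_results(tb, p3)
  js <- jsonlite::read_json(p3, simplifyVector = TRUE)
  expect_identical(js$trial, "PCVM")
  expect_true(!is.null(js$config$tol_deg))
})
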