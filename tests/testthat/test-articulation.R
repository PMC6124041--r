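# Chain posing, pivots, spacing reduction and rigid joint rotations.

test_that("neutral pose reproduces the declared intervertebral gaps", {
  col <- make_column(column_spec(n_vertebrae = 5, gap = c(1, 2, 3, 4)))
  pose <- neutral_pose(col)
  expect_true(all(pose$angles == 0))
  for (i in 1:4) {
    p <- neckROM:::world_landmark(pose, i, "posterior")
    a <- neckROM:::world_landmark(pose, i + 1, "anterior")
    expect_equal(sqrt(sum((p - a)^2)), i, tolerance = 1e-6)
  }
  # anterior axes collinear with the chain axis
  for (tr in pose$transforms) expect_equal(tr$R, diag(3), tolerance = 1e-12)
})

test_that("pivot sits midway between the facing centrum landmarks", {
  sp <- make_sphere_pair(1, 0.2, mesh_resolution = 16)
  pose <- neutral_pose(sp)
  jf <- compute_pivot(pose, 1)
  # 1.1 mm behind sphere A's centre along the chain axis
  expect_equal(jf$pivot, c(-1.1, 0, 0), tolerance = 1e-9)
  expect_equal(jf$gap, 0.2, tolerance = 1e-9)

  col <- symmetric_pair_column()
  jf2 <- compute_pivot(neutral_pose(col), 1)
  expect_lt(abs(jf2$pivot[2]), 1e-9) # median plane by symmetry
  expect_error(compute_pivot(pose, 5), "out of range")
})

test_that("spacing reduction closes each gap to within tolerance", {
  sp <- make_sphere_pair(1, 0.2, mesh_resolution = 48)
  pose <- reduce_spacing(neutral_pose(sp), epsilon_mm = 1e-3)
  expect_identical(pose$mode, "minimum")
  expect_gte(pose$reduction[1], 0.199)
  expect_lte(pose$reduction[1], 0.2)
  # pivot recomputed at the collapsed gap, within epsilon of the contact point
  jf <- compute_pivot(pose, 1)
  d <- mesh_distance(neckROM:::posed_vertebra(pose, 1)$parts$centrum,
                     neckROM:::posed_vertebra(pose, 2)$parts$centrum)
  expect_lt(sqrt(sum((jf$pivot - d$point_a)^2)), 1e-3 + 1e-6)

  # already-touching pair is a fixed point
  sp0 <- make_sphere_pair(1, 0, mesh_resolution = 16)
  pose0 <- reduce_spacing(neutral_pose(sp0), epsilon_mm = 1e-3)
  expect_identical(pose0$reduction[1], 0)
})

test_that("post-reduction centrum distances pass an exhaustive proximity scan", {
  eps <- 0.01
  col <- make_column(column_spec(n_vertebrae = 3, gap = c(1.5, 2.5)))
  pose <- neutral_pose(col, "minimum", epsilon_mm = eps)
  for (i in 1:2) {
    a <- neckROM:::posed_vertebra(pose, i)$parts$centrum
    b <- neckROM:::posed_vertebra(pose, i + 1)$parts$centrum
    # the closest features are rim vertices, so the vertex scan is exact here
    expect_lte(brute_mesh_dist(a, b), eps + 1e-6)
  }
})

test_that("re-expansion by the recorded translations recovers the preserved pose", {
  col <- make_column(column_spec(n_vertebrae = 3, gap = c(1.5, 2.5)))
  ref <- neutral_pose(col)
  back <- expand_spacing(reduce_spacing(neutral_pose(col), epsilon_mm = 0.01))
  for (i in seq_along(ref$transforms)) {
    expect_equal(back$transforms[[i]]$t, ref$transforms[[i]]$t,
                 tolerance = 1e-9)
    expect_equal(back$transforms[[i]]$R, ref$transforms[[i]]$R,
                 tolerance = 1e-12)
  }
})

test_that("joint rotations are rigid, invertible and order-stable", {
  col <- symmetric_pair_column()
  pose <- neutral_pose(col)
  v0 <- neckROM:::posed_vertebra(pose, 2)$parts$centrum$vertices

  p1 <- apply_rotation(pose, 1, "dorsal", 17)
  v1 <- neckROM:::posed_vertebra(p1, 2)$parts$centrum$vertices
  d0 <- as.matrix(stats::dist(v0[1:25, ]))
  d1 <- as.matrix(stats::dist(v1[1:25, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9) # intra-vertebra distances preserved

  p2 <- apply_rotation(p1, 1, "dorsal", -17)
  v2 <- neckROM:::posed_vertebra(p2, 2)$parts$centrum$vertices
  expect_lt(max(abs(v2 - v0)), 1e-9) # inverse recovers the start

  pa <- apply_rotation(apply_rotation(pose, 1, "lateral", 5), 1, "lateral", 7)
  pb <- apply_rotation(pose, 1, "lateral", 12)
  expect_equal(pa$transforms[[2]]$R, pb$transforms[[2]]$R, tolerance = 1e-9)
  expect_equal(pa$transforms[[2]]$t, pb$transforms[[2]]$t, tolerance = 1e-9)

  expect_error(apply_rotation(pose, 1, "twist", 5), "unknown profile")
  expect_error(apply_rotation(pose, 3, "dorsal", 5), "unknown joint")
  expect_error(apply_rotation(pose, 1, "dorsal", 200), "180")
})

test_that("rotating a sphere joint moves its centre on the closed-form circle", {
  r <- 1; g <- 0.2
  sp <- make_sphere_pair(r, g, mesh_resolution = 16)
  pose <- neutral_pose(sp)
  rho <- r + g / 2
  pivot <- c(-(r + g / 2), 0, 0)
  for (phi in c(10, 45, 90)) {
    p <- apply_rotation(pose, 1, "lateral", phi)
    ctr <- drop(p$transforms[[2]]$R %*% c(0, 0, 0)) + p$transforms[[2]]$t
    th <- phi * pi / 180
    # lateral bend is towards the right (negative y)
    expected <- pivot + rho * c(-cos(th), -sin(th), 0)
    expect_equal(ctr, expected, tolerance = 1e-9)
  }
})

test_that("whole-chain mode composes transforms down the column", {
  col <- make_column(column_spec(n_vertebrae = 4, gap = 2))
  pose <- neutral_pose(col)
  ch <- apply_rotation(pose, 1, "dorsal", 12, chain = TRUE)
  jf <- pose$joints[[1]]
  Rrot <- rotation_about(jf$axis_dorsoventral, 12)
  for (k in 2:4) {
    expect_equal(ch$transforms[[k]]$R, Rrot %*% pose$transforms[[k]]$R,
                 tolerance = 1e-12)
    expect_equal(ch$transforms[[k]]$t,
                 drop(Rrot %*% (pose$transforms[[k]]$t - jf$pivot)) + jf$pivot,
                 tolerance = 1e-9)
  }
  # pairwise mode leaves vertebrae behind the joint untouched
  pw <- apply_rotation(pose, 1, "dorsal", 12, chain = FALSE)
  expect_identical(pw$transforms[[3]], pose$transforms[[3]])
})

test_that("poses serialise to JSON and back", {
  dir <- withr::local_tempdir()
  col <- make_column(column_spec(n_vertebrae = 3, gap = 2))
  pose <- apply_rotation(neutral_pose(col), 1, "ventral", 8)
  path <- file.path(dir, "pose.json")
  write_pose_json(pose, path)
  back <- read_pose_json(path)
  expect_identical(back$mode, "preserved")
  for (i in 1:3) {
    expect_equal(back$transforms[[i]]$R, pose$transforms[[i]]$R,
                 tolerance = 1e-12)
    expect_equal(back$transforms[[i]]$t, pose$transforms[[i]]$t,
                 tolerance = 1e-12)
  }
  expect_equal(back$angles_deg$ventral[1], 8)
})
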