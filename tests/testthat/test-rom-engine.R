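# Contact queries, the bisection search against analytic oracles, trial
# orchestration and the virtual angle measurement.

test_that("contact queries on unit spheres match sphere arithmetic", {
  mk <- function(center_dist) {
    s <- neckROM:::sphere_mesh(1, 64)
    a <- vertebra_mesh("A", list(centrum = s),
                       landmarks = list(anterior = c(1, 0, 0),
                                        posterior = c(-1, 0, 0),
                                        dorsal = c(0, 0, 1)))
    sb <- tri_mesh(sweep(s$vertices, 2, c(-center_dist, 0, 0), `+`), s$faces)
    b <- vertebra_mesh("B", list(centrum = sb),
                       landmarks = list(anterior = c(-center_dist + 1, 0, 0),
                                        posterior = c(-center_dist - 1, 0, 0),
                                        dorsal = c(-center_dist, 0, 1)))
    list(a = a, b = b)
  }
  rule <- contact_rule(epsilon_mm = 0.1)
  close_pair <- mk(2.05)
  rep1 <- check_contact(close_pair$a, close_pair$b, rule)
  expect_true(rep1$in_contact)
  expect_equal(rep1$distance, 0.05, tolerance = 0.01)
  far_pair <- mk(2.2)
  rep2 <- check_contact(far_pair$a, far_pair$b, rule)
  expect_false(rep2$in_contact)
  expect_equal(rep2$distance, 0.2, tolerance = 0.01)
  expect_identical(rep2$pair, c("centrum", "centrum"))
  expect_error(check_contact(close_pair$a, close_pair$b,
                             contact_rule(include = list())),
               "rule error")
})

test_that("the distance kernel agrees with an exhaustive vertex-to-surface scan", {
  col <- make_column(column_spec(n_vertebrae = 2, gap = 2))
  pose <- neutral_pose(col)
  for (ang in c(0, 4, 8)) {
    p <- if (ang > 0) apply_rotation(pose, 1, "dorsal", ang) else pose
    a <- merge_vertebra(neckROM:::posed_vertebra(p, 1))
    b <- merge_vertebra(neckROM:::posed_vertebra(p, 2))
    impl <- mesh_distance(a, b)$distance
    oracle <- brute_mesh_dist(a, b)
    expect_lte(impl, oracle + 1e-9)  # vertex scan upper-bounds the true distance
    expect_lt(oracle - impl, 0.05)   # and is tight at this mesh resolution
  }
})

test_that("witness points realise the reported distance", {
  col <- make_column(column_spec(n_vertebrae = 2, gap = 2))
  pose <- neutral_pose(col)
  rep <- check_contact(neckROM:::posed_vertebra(pose, 1),
                       neckROM:::posed_vertebra(pose, 2), contact_rule())
  expect_equal(sqrt(sum((rep$point_a - rep$point_b)^2)), rep$distance,
               tolerance = 1e-9)
})

test_that("bisection reproduces the sphere-pair closed form", {
  # validate the closed form itself against an independent 0.01-degree sweep
  for (g in c(0.2, 0.5)) {
    expect_equal(sphere_sweep_oracle(1, g, 0.01), sphere_phi_star(1, g),
                 tolerance = 0.02)
  }
  tol <- 0.01
  res <- 32
  rule <- contact_rule(epsilon_mm = 1e-3)
  for (case in list(c(1, 0.2), c(0.5, 0.5))) {
    r <- case[1]; g <- case[2]
    pose <- neutral_pose(make_sphere_pair(r, g, res))
    out <- max_displacement(pose, 1, "lateral", rule, tol_deg = tol,
                            bracket_deg = 150)
    # discretisation bound: chord sagitta of both meshes plus the contact
    # tolerance, divided by the gap-closing rate at the contact angle
    phi <- sphere_phi_star(r, g) * pi / 180
    rho <- r + g / 2
    dDdphi <- rho^2 * sin(phi) / (2 * r)
    disc <- (2 * r * (1 - cos(sqrt(2) * pi / res)) + 1e-3) / dDdphi * 180 / pi
    expect_false(out$limit)
    expect_lt(abs(out$angle_deg - sphere_phi_star(r, g)), 2 * tol + disc)
  }
  # immediate contact reports zero
  pose0 <- neutral_pose(make_sphere_pair(1, 0, 32))
  expect_identical(max_displacement(pose0, 1, "lateral", rule)$angle_deg, 0)
})

test_that("left and right lateral maxima agree on symmetric fixtures", {
  col <- symmetric_pair_column()
  pose <- neutral_pose(col)
  rule <- contact_rule()
  right <- max_displacement(pose, 1, "lateral", rule, tol_deg = 0.01)
  left <- max_displacement(pose, 1, "lateral_left", rule, tol_deg = 0.01)
  expect_lt(abs(right$angle_deg - left$angle_deg), 0.05)
})

test_that("trials cover every joint and profile with sane bookkeeping", {
  col <- make_column(column_spec(n_vertebrae = 5, gap = 2))
  tb <- run_trial(col, "PCVM", tol_deg = 0.05)
  expect_identical(nrow(tb), 12L) # 4 joints x 3 profiles
  expect_true(all(tb$angle_deg >= 0))
  expect_true(all(!tb$missing))
  expect_true(all(tb$limit | !is.na(tb$stop_part_a)))
})

test_that("minimum-spacing results never exceed preserved-spacing results on convex fixtures", {
  col <- make_sphere_chain(3, 1, c(0.2, 0.5), mesh_resolution = 24)
  rule <- contact_rule(epsilon_mm = 1e-3)
  pcvm <- run_trial(col, "PCVM", rule, tol_deg = 0.05)
  mism <- run_trial(col, "MISM", rule, tol_deg = 0.05,
                    reduction_epsilon_mm = 1e-3, exclude_centra = FALSE)
  expect_true(all(mism$angle_deg <= pcvm$angle_deg + 1e-9))
  expect_true(all(mism$angle_deg == 0)) # starts in centrum contact
})

test_that("excluded centrum contact leaves a centra-only column bracket-limited", {
  col <- make_sphere_chain(2, 1, 0.3, mesh_resolution = 16)
  tb <- run_trial(col, "MISM", contact_rule(epsilon_mm = 1e-3), tol_deg = 0.1)
  expect_true(all(tb$limit))
  expect_true(all(tb$angle_deg == 90))
})

test_that("stopping parts on the gradient column follow the osteological inventory", {
  col <- make_column(default_column_spec(5))
  pcvm <- run_trial(col, "PCVM", tol_deg = 0.05)
  lat <- pcvm[pcvm$profile == "lateral", ]
  expect_true(all(grepl("cervical_rib", lat$stop_part_a)))
  expect_true(all(grepl("cervical_rib", lat$stop_part_b)))
  dors <- pcvm[pcvm$profile == "dorsal", ]
  expect_true(all(dors$stop_part_a %in%
                    c("neural_spine", "prezygapophysis_L", "prezygapophysis_R",
                      "postzygapophysis_L", "postzygapophysis_R")))
  vent <- pcvm[pcvm$profile == "ventral", ]
  expect_true(all(vent$stop_part_a == "centrum" & vent$stop_part_b == "centrum"))
})

test_that("damage masks flag affected joints but the trial continues", {
  spec <- column_spec(n_vertebrae = 4, gap = 2,
                      damage = list(C2 = c("neural_spine", "cervical_rib_L",
                                           "cervical_rib_R")))
  tb <- run_trial(make_column(spec), "PCVM", tol_deg = 0.05)
  expect_true(all(tb$flagged[tb$joint %in% c("C1-C2", "C2-C3")]))
  expect_true(all(!tb$flagged[tb$joint == "C3-C4"]))
  expect_true(all(!is.na(tb$angle_deg)))
})

test_that("identical inputs give identical ROM tables", {
  col <- make_column(column_spec(n_vertebrae = 3, gap = 2))
  t1 <- run_trial(col, "PCVM", tol_deg = 0.05)
  t2 <- run_trial(col, "PCVM", tol_deg = 0.05)
  expect_identical(t1, t2)
})

test_that("line-fitting measurement recovers the commanded joint angle", {
  col <- make_column(column_spec(n_vertebrae = 2, gap = 2))
  base <- neutral_pose(col)
  expect_equal(measure_line_angle(base, 1, "dorsal"), 0, tolerance = 1e-9)
  for (pf in c("lateral", "dorsal", "ventral")) {
    pose <- apply_rotation(base, 1, pf, 10)
    expect_lt(abs(measure_line_angle(pose, 1, pf) - 10), 0.1)
  }
  # triplicate protocol with measurement jitter
  pose15 <- apply_rotation(base, 1, "dorsal", 15)
  set.seed(11)
  m <- measure_line_angle(pose15, 1, "dorsal", replicates = 3,
                          jitter_sd_deg = 0.5)
  expect_lt(abs(m - 15), 3 * 0.5 / sqrt(3))
  expect_error(measure_line_angle(base, 4, "dorsal"), "state error")
})
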