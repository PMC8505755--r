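test_that("generated meshes satisfy all structural invariants", {
  mesh <- fixture_mesh()
  expect_true(validate_mesh(mesh))
  expect_true(all(mesh$element_volume > 0))
  # transmural coordinate lies in [0,1] everywhere
  expect_true(all(mesh$transmural >= 0 & mesh$transmural <= 1))
  # both ventricle labels present on endocardial nodes
  expect_setequal(unique(na.omit(mesh$ventricle)), c("LV", "RV"))
})

test_that("mesh generation is deterministic and scales geometrically", {
  ap <- anatomy_preset("small")
  m1 <- generate_synthetic_mesh(axes = ap$axes,
                                wall_thickness = ap$wall_thickness,
                                edge_length = 0.5)
  m2 <- generate_synthetic_mesh(axes = ap$axes,
                                wall_thickness = ap$wall_thickness,
                                edge_length = 0.5)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  # doubling all lengths (same thickness ratio) scales volume by 8
  m8 <- generate_synthetic_mesh(axes = 2 * ap$axes,
                                wall_thickness = 2 * ap$wall_thickness,
                                edge_length = 0.5)
  expect_lt(abs(m8$volume_cm3 / m1$volume_cm3 - 8) / 8, 0.05)
})

test_that("default large preset lands in the cohort volume range", {
  ap <- anatomy_preset("large")
  m <- generate_synthetic_mesh(axes = ap$axes,
                               wall_thickness = ap$wall_thickness,
                               edge_length = 0.5)
  expect_gte(m$volume_cm3, 74)
  expect_lte(m$volume_cm3, 171)
})

test_that("degenerate anatomy is rejected with an explanatory error", {
  expect_error(generate_synthetic_mesh(axes = c(2, 2, 5), wall_thickness = 2),
               "degenerate")
  expect_error(generate_synthetic_mesh(edge_length = 0.05), "edge_length")
})

test_that("helix angle follows the linear transmural rule", {
  # craft single-tet meshes with controlled transmural values
  for (case in list(list(tm = c(0, 0, 0, 0), expected = 60),
                    list(tm = c(1, 1, 1, 1), expected = -60),
                    list(tm = c(0.5, 0.5, 0.5, 0.5), expected = 0))) {
    m <- fake_tet_mesh(transmural = case$tm)
    m <- assign_fibre_frames(m, 60, -60)
    expect_equal(m$element_helix_deg, case$expected, tolerance = 1e-12)
    # fibre really is the circumferential axis rotated by alpha towards
    # the longitudinal axis
    alpha <- case$expected * pi / 180
    expect_equal(sum(m$fibre * m$axis_circ), cos(alpha), tolerance = 1e-9)
    expect_equal(sum(m$fibre * m$axis_long), sin(alpha), tolerance = 1e-9)
  }
  # frames orthonormal to 1e-9 on the real mesh
  mesh <- fixture_mesh()
  expect_lt(max(abs(rowSums(mesh$fibre * mesh$sheet))), 1e-9)
  expect_lt(max(abs(rowSums(mesh$fibre * mesh$normal))), 1e-9)
  expect_lt(max(abs(rowSums(mesh$fibre^2) - 1)), 1e-9)
  expect_error(assign_fibre_frames(
    structure(list(transmural = NULL), class = "bivmesh")), "transmural")
})

test_that("root candidate discretisation honours the coverage radii", {
  mesh <- fixture_mesh()
  low <- fixture_candidates("LOW")
  high <- fixture_candidates("HIGH")
  hybrid <- fixture_candidates("HYBRID")
  expect_lte(candidate_coverage(mesh, low)[["overall"]], 2.5)
  expect_lte(candidate_coverage(mesh, high)[["overall"]], 1.5)
  expect_gt(length(high$node_id), length(low$node_id))
  # hybrid = high-resolution LV + low-resolution RV
  expect_setequal(hybrid$node_id[hybrid$ventricle == "LV"],
                  high$node_id[high$ventricle == "LV"])
  expect_setequal(hybrid$node_id[hybrid$ventricle == "RV"],
                  low$node_id[low$ventricle == "RV"])
  # all candidates on endocardial nodes of the tagged ventricle
  expect_true(all(mesh$surface[low$node_id] %in% c("LV_ENDO", "RV_ENDO")))
  expect_identical(mesh$ventricle[low$node_id], low$ventricle)
})

test_that("electrode placement is anterior, external and scale-linear", {
  mesh <- fixture_mesh()
  el <- place_electrodes(mesh)
  expect_identical(sort(el$name),
                   sort(c("RA", "LA", "LL", "RL", paste0("V", 1:6))))
  heart_ctr <- colMeans(mesh$nodes)
  prec <- el[grepl("^V", el$name), ]
  expect_true(all(prec$x > heart_ctr[1]))          # anterior
  # outside the myocardial bounding box
  lo <- apply(mesh$nodes, 2, min); hi <- apply(mesh$nodes, 2, max)
  pos <- as.matrix(el[, c("x", "y", "z")])
  outside <- apply(pos, 1, function(p) any(p < lo) || any(p > hi))
  expect_true(all(outside))
  # doubling the torso scale doubles electrode-to-box-centre distances
  e1 <- place_electrodes(mesh, torso_scale = 1.3)
  e2 <- place_electrodes(mesh, torso_scale = 2.6)
  ctr <- (lo + hi) / 2
  d1 <- sqrt(rowSums((as.matrix(e1[, 2:4]) -
                        matrix(ctr, 10, 3, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((as.matrix(e2[, 2:4]) -
                        matrix(ctr, 10, 3, byrow = TRUE))^2))
  expect_equal(unname(d2 / d1), rep(2, 10), tolerance = 1e-12)
})

test_that("VTK and CSV mesh round trips are lossless", {
  mesh <- fixture_mesh()
  tmp <- withr::local_tempdir()
  vtk <- file.path(tmp, "mesh.vtk")
  write_mesh_vtk(mesh, vtk)
  m2 <- read_mesh_vtk(vtk, anatomy = mesh$anatomy)
  expect_equal(m2$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(m2$elements, mesh$elements)
  expect_identical(m2$surface, mesh$surface)
  expect_equal(m2$transmural, mesh$transmural, tolerance = 1e-12)
  expect_equal(m2$fibre, mesh$fibre, tolerance = 1e-12)

  write_mesh_csv(mesh, tmp)
  m3 <- read_mesh_csv(tmp, anatomy = mesh$anatomy)
  expect_equal(m3$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(m3$elements, mesh$elements)
  expect_identical(m3$surface, mesh$surface)
  expect_identical(m3$ventricle, mesh$ventricle)

  el <- fixture_electrodes()
  ef <- file.path(tmp, "el.csv")
  write_electrodes_csv(el, ef)
  expect_equal(read_electrodes_csv(ef)$x, el$x, tolerance = 1e-12)

  cand <- fixture_candidates("LOW")
  cf <- file.path(tmp, "cand.csv")
  write_candidates_csv(cand, cf)
  c2 <- read_candidates_csv(cf, "LOW")
  expect_identical(c2$node_id, cand$node_id)
  expect_identical(c2$ventricle, cand$ventricle)
})
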