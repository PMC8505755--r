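test_that("conduction speed and parameter-set invariants are enforced", {
  expect_error(conduction_speeds(99, 50, 32, 29), "endocardial")
  expect_error(conduction_speeds(150, 95, 32, 29), "myocardial")
  expect_error(conduction_speeds(150, 32, 50, 29), "ordering")
  expect_silent(conduction_speeds(150, 50, 50, 50))   # ties allowed
  sp <- conduction_speeds(300, 150, 100, 95, enforce_bounds = FALSE)
  expect_equal(sp[["endocardial"]], 300)
  cand <- fixture_candidates("LOW")
  sp <- speed_configurations()[["Normal speeds"]]
  expect_error(parameter_set(sp, rep(TRUE, 3)), "\\[6, 10\\]")
  act <- rep(FALSE, 20); act[1:11] <- TRUE
  expect_error(parameter_set(sp, act), "\\[6, 10\\]")
})

test_that("edge traversal time matches the anisotropic metric", {
  frame <- diag(3)                         # rows: fibre, sheet, normal
  sp <- speed_configurations()[["Normal speeds"]]   # 150/50/32/29
  # 1 cm along the fibre at 50 cm/s -> 20 ms
  expect_equal(edge_traversal_time(c(1, 0, 0), frame, sp), 20)
  # endocardial edge: 1.5 cm at 150 cm/s -> 10 ms
  expect_equal(edge_traversal_time(c(1.5, 0, 0), frame, sp,
                                   endocardial_edge = TRUE), 10)
  # oblique edge vs direct quadratic-form evaluation with M assembled
  # explicitly (independent matrix oracle)
  e <- c(1, 1, 0) / sqrt(2)
  vf <- 50; vs <- 32; vn <- 29
  M <- outer(c(1, 0, 0), c(1, 0, 0)) / vf^2 +
       outer(c(0, 1, 0), c(0, 1, 0)) / vs^2 +
       outer(c(0, 0, 1), c(0, 0, 1)) / vn^2
  expect_equal(edge_traversal_time(e, frame, sp),
               1000 * sqrt(drop(t(e) %*% M %*% e)), tolerance = 1e-12)
  # rotated frames: metric is frame-covariant
  th <- pi / 7
  R <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  Mr <- t(R) %*% diag(1 / c(vf, vs, vn)^2) %*% R
  expect_equal(edge_traversal_time(e, R, sp),
               1000 * sqrt(drop(t(e) %*% Mr %*% e)), tolerance = 1e-12)
  expect_error(edge_traversal_time(c(0, 0, 0), frame, sp), "zero-length")
})

test_that("activation equals brute-force shortest paths on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    g <- random_connected_graph()
    n_src <- sample(1:min(3, g$n), 1)
    sources <- sample.int(g$n, n_src)
    got <- cardioinfer:::.dijkstra_cpp(g$n, g$from - 1L, g$to - 1L, g$w,
                                       sources - 1L)
    want <- oracle_shortest_times(g$n, g$from, g$to, g$w, sources)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("a chain of endocardial edges activates additively", {
  # straight chain, 0.1 cm spacing, root at node 1, v_endo = 150 cm/s
  n <- 12
  graph <- structure(list(
    n_nodes = n, from0 = 0:(n - 2), to0 = 1:(n - 1),
    length_cm = rep(0.1, n - 1),
    proj_f = rep(0.1, n - 1), proj_s = rep(0, n - 1), proj_n = rep(0, n - 1),
    endocardial = rep(TRUE, n - 1)), class = "eikonal_graph")
  cand <- structure(list(node_id = 1L, ventricle = "LV", resolution = "LOW"),
                    class = "root_candidates")
  sp <- conduction_speeds(150, 50, 32, 29)
  act <- rep(FALSE, 12); act[1] <- TRUE
  ps <- structure(list(speeds = sp, root_active = c(TRUE)),
                  class = "parameter_set")
  atm <- simulate_activation(NULL, cand, ps, graph)
  expect_equal(atm$time_ms, (0:(n - 1)) * 0.1 / 150 * 1000,
               tolerance = 1e-12)
})

test_that("speed scaling divides activation times exactly", {
  mesh <- fixture_mesh()
  cand <- fixture_candidates("LOW")
  g <- fixture_graph()
  base <- fixture_params()
  atm0 <- simulate_activation(mesh, cand, base, g)
  for (c_ in c(0.5, 2)) {
    sp <- unclass(base$speeds) * c_
    ps <- parameter_set(conduction_speeds(sp[1], sp[2], sp[3], sp[4],
                                          enforce_bounds = FALSE),
                        base$root_active)
    atm <- simulate_activation(mesh, cand, ps, g)
    expect_equal(atm$time_ms, atm0$time_ms / c_, tolerance = 1e-12)
  }
})

test_that("adding a root node never increases any activation time", {
  mesh <- fixture_mesh()
  cand <- fixture_candidates("LOW")
  g <- fixture_graph()
  p6 <- fixture_params(n_roots = 6, seed = 7)
  act7 <- p6$root_active
  act7[which(!act7)[1]] <- TRUE
  p7 <- parameter_set(p6$speeds, act7)
  t6 <- simulate_activation(mesh, cand, p6, g)$time_ms
  t7 <- simulate_activation(mesh, cand, p7, g)$time_ms
  expect_true(all(t7 <= t6 + 1e-12))
})

test_that("isotropic propagation on a regular grid approaches Euclidean", {
  # 6x6x3 lattice, spacing 0.1 cm, first+second order edges, one corner
  # source; the graph metric over-estimates Euclidean distance by a
  # bounded metrication factor
  pts <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:2)) * 0.1
  n <- nrow(pts)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((pts[pairs[, 1], ] - pts[pairs[, 2], ])^2))
  keep <- d < 0.21                       # first and second neighbours
  pairs <- pairs[keep, ]; d <- d[keep]
  v <- 60
  graph <- structure(list(
    n_nodes = n, from0 = pairs[, 1] - 1L, to0 = pairs[, 2] - 1L,
    length_cm = d, proj_f = d, proj_s = rep(0, length(d)),
    proj_n = rep(0, length(d)), endocardial = rep(FALSE, length(d))),
    class = "eikonal_graph")
  # isotropic: all myocardial speeds equal
  sp <- conduction_speeds(150, v, v, v, enforce_bounds = FALSE)
  cand <- structure(list(node_id = 1L, ventricle = "LV", resolution = "LOW"),
                    class = "root_candidates")
  ps <- structure(list(speeds = sp, root_active = TRUE),
                  class = "parameter_set")
  t_ <- simulate_activation(NULL, cand, ps, graph)$time_ms
  t_euclid <- sqrt(rowSums((pts - matrix(pts[1, ], n, 3, byrow = TRUE))^2)) /
    v * 1000
  expect_true(all(t_ >= t_euclid - 1e-9))          # from above
  expect_lt(max((t_ - t_euclid) / pmax(t_euclid, 1e-9)), 0.16)
})

test_that("epicardial restriction is a projection", {
  mesh <- fixture_mesh()
  atm <- fixture_atm()
  epi <- extract_epicardial_map(atm, mesh)
  expect_equal(length(epi$node_id), sum(mesh$surface == "EPI"))
  expect_identical(epi$time_ms, atm$time_ms[mesh$surface == "EPI"])
  epi2 <- extract_epicardial_map(epi, mesh)
  expect_identical(epi2$time_ms, epi$time_ms)      # idempotent
  # root nodes fire at exactly zero; all times finite and non-negative
  roots <- fixture_candidates("LOW")$node_id[fixture_params()$root_active]
  expect_equal(min(atm$time_ms[roots]), 0)
  expect_true(all(is.finite(atm$time_ms)) && all(atm$time_ms >= 0))
})

test_that("unreachable nodes produce an identifying error", {
  graph <- structure(list(
    n_nodes = 3, from0 = 0L, to0 = 1L, length_cm = 0.1,
    proj_f = 0.1, proj_s = 0, proj_n = 0, endocardial = FALSE),
    class = "eikonal_graph")
  cand <- structure(list(node_id = 1L, ventricle = "LV", resolution = "LOW"),
                    class = "root_candidates")
  ps <- structure(list(speeds = conduction_speeds(150, 50, 32, 29),
                       root_active = TRUE), class = "parameter_set")
  expect_error(simulate_activation(NULL, cand, ps, graph), "unreachable")
})
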