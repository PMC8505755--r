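# Shared fixtures (memoised: the coarse mesh is built once per test run)
# and independent oracles used by the derived-value tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture_mesh <- function() {
  if (is.null(.fixture_cache$mesh)) {
    ap <- anatomy_preset("medium")
    .fixture_cache$mesh <- generate_synthetic_mesh(
      axes = ap$axes, wall_thickness = ap$wall_thickness,
      edge_length = 0.5, rv_bulge = ap$rv_bulge,
      rv_halfwidth_deg = ap$rv_halfwidth_deg, rv_apex_deg = ap$rv_apex_deg)
  }
  .fixture_cache$mesh
}

fixture_candidates <- function(resolution = "LOW") {
  key <- paste0("cand_", resolution)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- discretise_root_candidates(fixture_mesh(),
                                                        resolution)
  .fixture_cache[[key]]
}

fixture_graph <- function() {
  if (is.null(.fixture_cache$graph))
    .fixture_cache$graph <- eikonal_graph(fixture_mesh())
  .fixture_cache$graph
}

fixture_electrodes <- function() {
  if (is.null(.fixture_cache$elec))
    .fixture_cache$elec <- place_electrodes(fixture_mesh())
  .fixture_cache$elec
}

fixture_lead_field <- function() {
  if (is.null(.fixture_cache$lf))
    .fixture_cache$lf <- lead_field(fixture_mesh(), fixture_electrodes())
  .fixture_cache$lf
}

fixture_params <- function(speeds = speed_configurations()[["Normal speeds"]],
                           n_roots = 7, seed = 42) {
  cand <- fixture_candidates("LOW")
  set.seed(seed)
  act <- rep(FALSE, length(cand$node_id))
  act[sample.int(length(act), n_roots)] <- TRUE
  parameter_set(speeds, act)
}

fixture_atm <- function(...) {
  if (is.null(.fixture_cache$atm))
    .fixture_cache$atm <- simulate_activation(fixture_mesh(),
                                              fixture_candidates("LOW"),
                                              fixture_params(),
                                              fixture_graph())
  .fixture_cache$atm
}

# ---- independent oracles ---------------------------------------------------

# brute-force multi-source shortest paths by exhaustive DFS over simple
# paths (usable up to ~10 nodes / ~20 edges)
oracle_shortest_times <- function(n, from, to, w, sources) {
  adj <- vector("list", n)
  for (e in seq_along(from)) {
    adj[[from[e]]] <- rbind(adj[[from[e]]], c(to[e], w[e]))
    adj[[to[e]]] <- rbind(adj[[to[e]]], c(from[e], w[e]))
  }
  best <- rep(Inf, n)
  dfs <- function(v, cost, visited) {
    if (cost < best[v]) best[v] <<- cost
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, cost + nb[r, 2], visited)
        visited[u] <- FALSE
      }
    }
  }
  for (s in sources) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    dfs(s, 0, visited)
  }
  best
}

# random connected undirected graph with positive weights
random_connected_graph <- function(n_max = 10, m_max = 20) {
  n <- sample(2:n_max, 1)
  # spanning tree first, then extra edges
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    from <- c(from, u); to <- c(to, v)
  }
  extra <- sample(0:max(0, min(m_max - (n - 1), n * (n - 1) / 2 - (n - 1))), 1)
  tries <- 0
  while (extra > 0 && tries < 100) {
    a <- sample.int(n, 2)
    key_new <- paste(min(a), max(a))
    keys <- paste(pmin(from, to), pmax(from, to))
    tries <- tries + 1
    if (!key_new %in% keys) {
      from <- c(from, min(a)); to <- c(to, max(a))
      extra <- extra - 1
    }
  }
  list(n = n, from = from, to = to,
       w = round(runif(length(from), 0.1, 5), 3))
}

# exhaustive enumeration of admissible constrained-DTW paths; shares only
# the *problem definition* (band mask, penalty schedule) with the
# implementation, not its dynamic programme
oracle_dtw <- function(a, b, cfg = dtw_config()) {
  n <- length(a); m <- length(b)
  start_w <- cfg$start_penalty_weight
  if (is.null(start_w)) start_w <- 0.2 * diff(range(b))
  end_w <- cfg$end_penalty_weight
  mask <- dtw_band_mask(n, m, cfg)
  pen <- function(i, j) {
    pi_ <- if (n > 1) (i - 1) / (n - 1) else 1
    pj_ <- if (m > 1) (j - 1) / (m - 1) else 1
    p <- (pi_ + pj_) / 2
    start_w + (end_w - start_w) * p
  }
  best <- Inf
  best_len <- NA_integer_
  rec <- function(i, j, cost, dir, run, len) {
    if (cost >= best) return()
    if (i == n && j == m) {
      if (cost < best) { best <<- cost; best_len <<- len }
      return()
    }
    # diagonal
    if (i < n && j < m && mask[i + 1, j + 1])
      rec(i + 1, j + 1, cost + abs(a[i + 1] - b[j + 1]), 0L, 0L, len + 1L)
    # vertical (a advances)
    if (i < n && mask[i + 1, j] && !(dir == 1L && run >= 2L))
      rec(i + 1, j, cost + abs(a[i + 1] - b[j]) + pen(i + 1, j), 1L,
          if (dir == 1L) run + 1L else 1L, len + 1L)
    # horizontal (b advances)
    if (j < m && mask[i, j + 1] && !(dir == 2L && run >= 2L))
      rec(i, j + 1, cost + abs(a[i] - b[j + 1]) + pen(i, j + 1), 2L,
          if (dir == 2L) run + 1L else 1L, len + 1L)
  }
  if (mask[1, 1]) rec(1L, 1L, abs(a[1] - b[1]), 0L, 0L, 1L)
  if (!is.finite(best)) return(list(feasible = FALSE))
  list(feasible = TRUE, total_cost = best)
}

# admissibility check for a returned DTW path
check_dtw_path <- function(path, n, m, cfg = dtw_config()) {
  mask <- dtw_band_mask(n, m, cfg)
  if (!all(path[1, ] == c(1, 1)) || !all(path[nrow(path), ] == c(n, m)))
    return("endpoint violation")
  run <- 0L; dir <- 0L
  for (r in 2:nrow(path)) {
    di <- path[r, 1] - path[r - 1, 1]
    dj <- path[r, 2] - path[r - 1, 2]
    if (!((di == 1 && dj == 1) || (di == 1 && dj == 0) ||
          (di == 0 && dj == 1)))
      return("non-monotone step")
    d <- if (di == 1 && dj == 1) 0L else if (di == 1) 1L else 2L
    run <- if (d != 0L && d == dir) run + 1L else if (d != 0L) 1L else 0L
    dir <- d
    if (run > 2L) return("slope violation")
    if (!mask[path[r, 1], path[r, 2]]) return("band violation")
  }
  "ok"
}

# minimal hand-built mesh (single tetrahedron) for unit-level tests
fake_tet_mesh <- function(nodes = rbind(c(0, 0, 0), c(0.1, 0, 0),
                                        c(0, 0.1, 0), c(0, 0, 0.1)),
                          transmural = c(0, 0, 0, 1)) {
  surface <- c("LV_ENDO", "LV_ENDO", "RV_ENDO", "EPI")
  vol <- abs(cardioinfer:::.tet_volumes(nodes, matrix(1:4, 1)))
  m <- structure(list(nodes = nodes, elements = matrix(1:4, 1),
                      surface = surface,
                      ventricle = c("LV", "LV", "RV", NA),
                      transmural = transmural, element_volume = vol,
                      volume_cm3 = sum(vol),
                      anatomy = list(axes = c(1, 1, 1), wall_thickness = 0.5,
                                     edge_length = 0.1)),
                 class = "bivmesh")
  cardioinfer:::.element_local_axes(m)
}
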