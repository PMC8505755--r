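# Anisotropic graph-Eikonal activation model.
#
# Conduction is orthotropic in the myocardium (fast along fibres, slower
# across sheets, slowest along the sheet-normal) and isotropic and fast in
# a thin endocardial layer emulating the Purkinje network.  Activation
# times are first-arrival times from the active root nodes, computed by
# multi-source Dijkstra on the mesh graph.

#' Construct a validated set of conduction speeds
#'
#' Speeds are in cm/s.  The endocardial (Purkinje-layer) speed must lie in
#' `[100, 200]`; the three myocardial speeds in `[25, 90]` with the ordering
#' fibre >= sheet >= sheet-normal (ties tolerated to 1e-9).
#'
#' @param endocardial,fibre,sheet,sheet_normal speeds in cm/s.
#' @param enforce_bounds set `FALSE` to skip the physiological range checks
#'   (the ordering is always enforced); used for diagnostics such as global
#'   speed-scaling studies.  Inference always keeps bounds on.
#' @return object of class `conduction_speeds` (named numeric of length 4).
#' @export
conduction_speeds <- function(endocardial, fibre, sheet, sheet_normal,
                              enforce_bounds = TRUE) {
  v <- c(endocardial = as.numeric(endocardial), fibre = as.numeric(fibre),
         sheet = as.numeric(sheet), sheet_normal = as.numeric(sheet_normal))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("conduction speeds must be finite and positive")
  if (enforce_bounds) {
    if (endocardial < 100 - 1e-9 || endocardial > 200 + 1e-9)
      stop("endocardial speed must lie in [100, 200] cm/s")
    myo <- c(fibre, sheet, sheet_normal)
    if (any(myo < 25 - 1e-9) || any(myo > 90 + 1e-9))
      stop("myocardial speeds must lie in [25, 90] cm/s")
  }
  if (fibre < sheet - 1e-9 || sheet < sheet_normal - 1e-9)
    stop("speed ordering violated: need fibre >= sheet >= sheet-normal")
  structure(v, class = "conduction_speeds")
}

#' Construct a parameter-set (speeds + active root nodes)
#'
#' @param speeds a `conduction_speeds`.
#' @param root_active logical vector over the candidate root nodes; between
#'   6 and 10 entries must be active.
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(speeds, root_active) {
  stopifnot(inherits(speeds, "conduction_speeds"), is.logical(root_active))
  k <- sum(root_active)
  if (k < 6 || k > 10)
    stop("number of active root nodes must lie in [6, 10], got ", k)
  structure(list(speeds = speeds, root_active = root_active),
            class = "parameter_set")
}

#' Traversal time of a single graph edge
#'
#' Myocardial edges use the orthotropic metric
#' `t = 1000 * sqrt(e' M e)` ms with
#' `M = f f'/v_f^2 + s s'/v_s^2 + n n'/v_n^2`; endocardial edges (both
#' endpoints on the same endocardial surface) are isotropic:
#' `t = 1000 * |e| / v_endo`.
#'
#' @param edge_vector displacement in cm (length-3 numeric).
#' @param frame 3x3 matrix whose rows are the orthonormal fibre, sheet and
#'   sheet-normal unit vectors.
#' @param speeds a `conduction_speeds`.
#' @param endocardial_edge logical flag.
#' @return traversal time in ms (always positive).
#' @export
edge_traversal_time <- function(edge_vector, frame, speeds,
                                endocardial_edge = FALSE) {
  e <- as.numeric(edge_vector)
  len <- sqrt(sum(e^2))
  if (len == 0) stop("zero-length edge")
  if (endocardial_edge) return(1000 * len / speeds[["endocardial"]])
  proj <- as.numeric(frame %*% e)
  1000 * sqrt((proj[1] / speeds[["fibre"]])^2 +
              (proj[2] / speeds[["sheet"]])^2 +
              (proj[3] / speeds[["sheet_normal"]])^2)
}

#' Precompute the Eikonal propagation graph of a mesh
#'
#' The graph contains all element (tetrahedron) edges plus
#' neighbour-of-neighbour node pairs, which reduces the metrication error of
#' shortest-path wavefront propagation on a graph.  Each edge carries its
#' projections on a per-edge frame (the volume-weighted average of the
#' frames of elements adjacent to either endpoint, re-orthonormalised) and
#' an endocardial-layer flag (both endpoints on the same endocardial
#' surface).
#'
#' @param mesh a `bivmesh` with fibre frames.
#' @param second_order include neighbour-of-neighbour edges (default TRUE).
#' @return object of class `eikonal_graph` with 0-based edge arrays for the
#'   compiled solver.
#' @export
eikonal_graph <- function(mesh, second_order = TRUE) {
  stopifnot(inherits(mesh, "bivmesh"))
  if (is.null(mesh$fibre)) stop("mesh has no fibre frames")
  n <- nrow(mesh$nodes)
  el <- mesh$elements
  pair_idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  fr <- el[, pair_idx[, 1]]
  to <- el[, pair_idx[, 2]]
  ij <- cbind(pmin(as.vector(fr), as.vector(to)),
              pmax(as.vector(fr), as.vector(to)))
  A1 <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                             dims = c(n, n), symmetric = TRUE)
  A1 <- A1 != 0
  if (second_order) {
    A2 <- (A1 %*% A1) != 0
    A <- A1 | A2
  } else {
    A <- A1
  }
  At <- Matrix::triu(A, k = 1)
  idx <- Matrix::which(At)                 # column-major linear index
  from <- as.integer((idx - 1) %% n) + 1L
  to <- as.integer((idx - 1) %/% n) + 1L

  evec <- mesh$nodes[to, , drop = FALSE] - mesh$nodes[from, , drop = FALSE]
  len <- sqrt(rowSums(evec^2))

  # volume-weighted frame sums per node, then per-edge re-orthonormalisation
  inc <- Matrix::sparseMatrix(i = as.vector(el),
                              j = rep(seq_len(nrow(el)), times = 4),
                              x = 1, dims = c(n, nrow(el)))
  wf <- as.matrix(inc %*% (mesh$fibre * mesh$element_volume))
  ws <- as.matrix(inc %*% (mesh$sheet * mesh$element_volume))
  f_avg <- wf[from, , drop = FALSE] + wf[to, , drop = FALSE]
  s_avg <- ws[from, , drop = FALSE] + ws[to, , drop = FALSE]
  f_hat <- .normalise_rows(f_avg)
  s_avg <- s_avg - f_hat * rowSums(s_avg * f_hat)
  s_hat <- .normalise_rows(s_avg)
  n_hat <- .row_cross(f_hat, s_hat)

  endo <- !is.na(mesh$ventricle[from]) & !is.na(mesh$ventricle[to]) &
    mesh$surface[from] == mesh$surface[to]

  structure(list(
    n_nodes = n,
    from0 = from - 1L, to0 = to - 1L,
    length_cm = len,
    proj_f = abs(rowSums(evec * f_hat)),
    proj_s = abs(rowSums(evec * s_hat)),
    proj_n = abs(rowSums(evec * n_hat)),
    endocardial = endo
  ), class = "eikonal_graph")
}

# per-edge traversal times for a given speed set
.edge_weights <- function(graph, speeds) {
  w <- 1000 * sqrt((graph$proj_f / speeds[["fibre"]])^2 +
                   (graph$proj_s / speeds[["sheet"]])^2 +
                   (graph$proj_n / speeds[["sheet_normal"]])^2)
  w[graph$endocardial] <- 1000 * graph$length_cm[graph$endocardial] /
    speeds[["endocardial"]]
  w
}

#' Simulate the ventricular activation time map for a parameter-set
#'
#' Multi-source Dijkstra from all active root nodes (all firing at t = 0)
#' over the propagation graph with anisotropic edge traversal times.
#'
#' @param mesh a `bivmesh`.
#' @param candidates a `root_candidates` object.
#' @param params a `parameter_set`.
#' @param graph optional precomputed [eikonal_graph()] (recommended inside
#'   loops).
#' @return object of class `activation_map`: `node_id` (1-based), `time_ms`,
#'   and the generating `params`.
#' @export
simulate_activation <- function(mesh, candidates, params, graph = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  if (length(params$root_active) != length(candidates$node_id))
    stop("root_active length does not match the candidate set")
  if (is.null(graph)) graph <- eikonal_graph(mesh)
  sources <- candidates$node_id[params$root_active]
  if (length(sources) == 0) stop("at least one active root node is required")
  w <- .edge_weights(graph, params$speeds)
  times <- .dijkstra_cpp(graph$n_nodes, graph$from0, graph$to0, w,
                         as.integer(sources) - 1L)
  if (any(!is.finite(times))) {
    bad <- which(!is.finite(times))
    stop("unreachable mesh node(s): ", paste(head(bad - 1L, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  structure(list(node_id = seq_len(graph$n_nodes), time_ms = times,
                 params = params), class = "activation_map")
}

#' Restrict an activation map to the epicardial surface
#'
#' @param atm an `activation_map`.
#' @param mesh the mesh it was computed on.
#' @return an `activation_map` containing only nodes labelled `EPI`
#'   (original node indexing preserved).
#' @export
extract_epicardial_map <- function(atm, mesh) {
  stopifnot(inherits(atm, "activation_map"))
  keep <- which(mesh$surface[atm$node_id] == "EPI")
  structure(list(node_id = atm$node_id[keep], time_ms = atm$time_ms[keep],
                 params = atm$params), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("Activation map: %d nodes, times %.1f-%.1f ms\n",
              length(x$node_id), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}
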