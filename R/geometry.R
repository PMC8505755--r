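#' @useDynLib cardioinfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd cor runif rnorm quantile
#' @importFrom utils read.csv write.csv head tail
NULL

SURFACE_LEVELS <- c("INTERIOR", "LV_ENDO", "RV_ENDO", "EPI")

#' Anatomy parameter presets for the synthetic biventricular geometry
#'
#' Returns ellipsoid semi-axes (cm), wall thickness (cm) and right-ventricular
#' bulge settings for four heart sizes.  The presets span the biventricular
#' myocardial volume range of healthy adult hearts (roughly 70--175 cm^3),
#' so a cohort built from all four covers realistic anatomical variability.
#'
#' @param name one of `"small"`, `"medium"`, `"large"`, `"xlarge"`.
#' @return named list of anatomy parameters accepted by
#'   [generate_synthetic_mesh()].
#' @export
anatomy_preset <- function(name = c("small", "medium", "large", "xlarge")) {
  name <- match.arg(name)
  base <- list(rv_bulge = 0.60, rv_halfwidth_deg = 82, rv_apex_deg = 142)
  dims <- switch(name,
    small  = list(axes = c(2.70, 2.60, 6.00), wall_thickness = 0.85),
    medium = list(axes = c(3.00, 2.90, 6.60), wall_thickness = 0.95),
    large  = list(axes = c(3.30, 3.20, 7.20), wall_thickness = 1.05),
    xlarge = list(axes = c(3.45, 3.35, 7.45), wall_thickness = 1.08))
  c(dims, base, list(preset = name))
}

# point grid on an ellipsoid patch; u = longitude, th = colatitude
.ellipsoid_point <- function(axes, u, th) {
  cbind(axes[1] * sin(th) * cos(u),
        axes[2] * sin(th) * sin(u),
        axes[3] * cos(th))
}

# signed volumes of tetrahedra (rows of 1-based node indices)
.tet_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  p4 <- nodes[elements[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c <- p4 - p1
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
         a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
         a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  det / 6
}

.normalise_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Generate a synthetic torso-biventricular mesh
#'
#' Builds a tetrahedral mesh of an idealised biventricular myocardium: the
#' left ventricle is a truncated thick-walled ellipsoid (apex-to-base axis =
#' z, base truncated above the equator) and the right ventricle is a thinner
#' crescent cavity carved into an outward bulge of the wall on the +x
#' (anterior) side.  The construction is a structured (longitude x latitude x
#' transmural) hexahedral grid split into five tetrahedra per cell with
#' parity alternation, so the mesh is conformal and fully deterministic.
#'
#' Surface labels mark the LV endocardium (inner shell), RV endocardium
#' (both faces of the carved cavity) and epicardium (outer shell).  The
#' transmural coordinate is the normalised distance ratio
#' d_endo / (d_endo + d_epi) between the labelled endocardial and epicardial
#' surfaces.  Fibre/sheet/sheet-normal frames are assigned by
#' [assign_fibre_frames()] with the default 60 to -60 degree transmural
#' helix-angle rule.
#'
#' @param axes outer ellipsoid semi-axes `c(a, b, c)` in cm (c = long axis).
#' @param wall_thickness LV wall thickness in cm; must be smaller than every
#'   semi-axis.
#' @param edge_length target edge length in cm, in `[0.1, 0.5]`.
#' @param seed integer; kept for interface symmetry (the construction itself
#'   is deterministic).
#' @param rv_bulge relative outward bulge of the wall over the RV sector.
#' @param rv_halfwidth_deg angular half-width of the RV sector (degrees).
#' @param rv_apex_deg colatitude (degrees) at which the RV cavity ends
#'   towards the apex.
#' @param endo_angle_deg,epi_angle_deg fibre helix angles at endocardium and
#'   epicardium (degrees).
#' @return an object of class `bivmesh`; see Details for fields.
#' @export
generate_synthetic_mesh <- function(axes = anatomy_preset("large")$axes,
                                    wall_thickness = 1.05,
                                    edge_length = 0.5,
                                    seed = 1L,
                                    rv_bulge = 0.60,
                                    rv_halfwidth_deg = 82,
                                    rv_apex_deg = 142,
                                    endo_angle_deg = 60,
                                    epi_angle_deg = -60) {
  axes <- as.numeric(axes)
  if (length(axes) != 3 || any(!is.finite(axes)) || any(axes <= 0))
    stop("`axes` must be three positive semi-axes in cm")
  if (!is.finite(wall_thickness) || wall_thickness <= 0)
    stop("`wall_thickness` must be positive")
  if (wall_thickness >= min(axes))
    stop("degenerate anatomy: wall_thickness (", wall_thickness,
         " cm) must be smaller than every semi-axis (min ", min(axes), " cm)")
  if (edge_length < 0.1 || edge_length > 0.5)
    stop("`edge_length` must lie in [0.1, 0.5] cm")

  h <- edge_length
  inner <- axes - wall_thickness
  th_base <- 70 * pi / 180
  th_apex <- 170 * pi / 180
  th_rv <- rv_apex_deg * pi / 180
  u_hw <- rv_halfwidth_deg * pi / 180

  # grid resolution; n_u must be even for the parity-alternating tet split
  n_u <- 2L * max(8L, as.integer(round(pi * mean(axes[1:2]) * 0.85 / h)))
  n_v <- max(6L, as.integer(round(0.9 * axes[3] * (th_apex - th_base) / h)))
  n_w <- max(4L, as.integer(round(wall_thickness / h)) + 2L)

  u <- 2 * pi * (seq_len(n_u) - 1L) / n_u          # wraps
  th <- seq(th_base, th_apex, length.out = n_v + 1L)

  # per-column bulge factor (multiplicative, on the outer surface only)
  su <- ifelse(abs(((u + pi) %% (2 * pi)) - pi) < u_hw,
               cos(pi / 2 * (((u + pi) %% (2 * pi)) - pi) / u_hw)^2, 0)
  sth <- ifelse(th <= th_rv,
                sin(pi * (th_rv - th) / (th_rv - th_base)), 0)
  sth[sth < 0] <- 0
  beta <- outer(su, sth) * rv_bulge                 # n_u x (n_v+1)

  # cavity columns: well inside the bulged sector
  cavity <- beta >= 0.35 * rv_bulge
  k_a <- max(1L, as.integer(round(n_w / 3)))
  k_b <- n_w - 1L
  if (k_b <= k_a + 1L) stop("radial resolution too coarse for the RV cavity")

  # node ids: id[i, j, k+1]; NA where the RV cavity removes stations
  exists_k <- function(i, j, k) !cavity[i, j] | k <= k_a | k >= k_b
  id <- array(NA_integer_, dim = c(n_u, n_v + 1L, n_w + 1L))
  coords <- matrix(0, nrow = n_u * (n_v + 1L) * (n_w + 1L), ncol = 3)
  cnt <- 0L
  for (j in seq_len(n_v + 1L)) {
    p_in <- .ellipsoid_point(inner, u, th[j])
    p_out <- .ellipsoid_point(axes, u, th[j])
    p_out[, 1:2] <- p_out[, 1:2] * (1 + beta[, j])
    for (k in 0:n_w) {
      w <- k / n_w
      pts <- p_in * (1 - w) + p_out * w
      for (i in seq_len(n_u)) {
        if (exists_k(i, j, k)) {
          cnt <- cnt + 1L
          id[i, j, k + 1L] <- cnt
          coords[cnt, ] <- pts[i, ]
        }
      }
    }
  }
  nodes <- coords[seq_len(cnt), , drop = FALSE]

  # hexahedra -> 5 tets with parity alternation (conformal across faces)
  even_split <- rbind(c(1, 2, 3, 5), c(4, 2, 3, 8), c(6, 2, 5, 8),
                      c(7, 3, 5, 8), c(2, 3, 5, 8))
  odd_split <- rbind(c(2, 1, 4, 6), c(3, 1, 4, 7), c(5, 1, 6, 7),
                     c(8, 4, 6, 7), c(1, 4, 6, 7))
  # corner order: (i,j,k),(i+1,j,k),(i,j+1,k),(i+1,j+1,k), then k+1 layer
  elems <- vector("list", n_u * n_v * n_w)
  ne <- 0L
  for (k in seq_len(n_w)) {
    for (j in seq_len(n_v)) {
      for (i in seq_len(n_u)) {
        i2 <- if (i == n_u) 1L else i + 1L
        corner <- c(id[i, j, k], id[i2, j, k], id[i, j + 1L, k],
                    id[i2, j + 1L, k], id[i, j, k + 1L], id[i2, j, k + 1L],
                    id[i, j + 1L, k + 1L], id[i2, j + 1L, k + 1L])
        if (anyNA(corner)) next
        split <- if ((i + j + k) %% 2L == 0L) even_split else odd_split
        ne <- ne + 1L
        elems[[ne]] <- matrix(corner[t(split)], ncol = 4, byrow = TRUE)
      }
    }
  }
  elements <- do.call(rbind, elems[seq_len(ne)])

  # orient all tets positively
  vol <- .tet_volumes(nodes, elements)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- elements[flip, 3L]
    elements[flip, 3L] <- elements[flip, 4L]
    elements[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0)) stop("internal error: degenerate tetrahedra produced")

  # surface labels
  surface <- rep("INTERIOR", nrow(nodes))
  lv_ids <- id[, , 1L]
  surface[lv_ids[!is.na(lv_ids)]] <- "LV_ENDO"
  epi_ids <- id[, , n_w + 1L]
  surface[epi_ids[!is.na(epi_ids)]] <- "EPI"
  for (j in seq_len(n_v + 1L)) {
    for (i in seq_len(n_u)) {
      if (cavity[i, j]) {
        surface[id[i, j, k_a + 1L]] <- "RV_ENDO"
        surface[id[i, j, k_b + 1L]] <- "RV_ENDO"
      }
    }
  }
  ventricle <- rep(NA_character_, nrow(nodes))
  ventricle[surface == "LV_ENDO"] <- "LV"
  ventricle[surface == "RV_ENDO"] <- "RV"

  transmural <- .transmural_coordinate(nodes, surface)

  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    surface = surface,
    ventricle = ventricle,
    transmural = transmural,
    element_volume = vol,
    volume_cm3 = sum(vol),
    anatomy = list(axes = axes, wall_thickness = wall_thickness,
                   edge_length = edge_length, rv_bulge = rv_bulge,
                   rv_halfwidth_deg = rv_halfwidth_deg,
                   rv_apex_deg = rv_apex_deg, seed = as.integer(seed))
  ), class = "bivmesh")
  mesh <- .element_local_axes(mesh)
  assign_fibre_frames(mesh, endo_angle_deg, epi_angle_deg)
}

# normalised wall-depth: distance ratio between labelled surfaces
.transmural_coordinate <- function(nodes, surface) {
  endo <- nodes[surface %in% c("LV_ENDO", "RV_ENDO"), , drop = FALSE]
  epi <- nodes[surface == "EPI", , drop = FALSE]
  if (nrow(endo) == 0 || nrow(epi) == 0)
    stop("both endocardial and epicardial surfaces must be non-empty")
  d_endo <- .min_dist_to_set(nodes, endo)
  d_epi <- .min_dist_to_set(nodes, epi)
  tm <- d_endo / (d_endo + d_epi)
  tm[surface %in% c("LV_ENDO", "RV_ENDO")] <- 0
  tm[surface == "EPI"] <- 1
  tm
}

# chunked nearest-distance from each row of `pts` to the point set `set`
.min_dist_to_set <- function(pts, set) {
  n <- nrow(pts)
  out <- numeric(n)
  step <- max(1L, as.integer(2e6 / nrow(set)))
  s2 <- rowSums(set^2)
  for (start in seq(1L, n, by = step)) {
    idx <- start:min(n, start + step - 1L)
    p <- pts[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), s2, "+") - 2 * p %*% t(set)
    d2[d2 < 0] <- 0
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# local circumferential / longitudinal / transmural axes per element,
# orthonormalised; transmural axis from the outer-ellipsoid surface normal
.element_local_axes <- function(mesh) {
  cent <- (mesh$nodes[mesh$elements[, 1], , drop = FALSE] +
           mesh$nodes[mesh$elements[, 2], , drop = FALSE] +
           mesh$nodes[mesh$elements[, 3], , drop = FALSE] +
           mesh$nodes[mesh$elements[, 4], , drop = FALSE]) / 4
  axes <- mesh$anatomy$axes
  e_t <- .normalise_rows(cbind(cent[, 1] / axes[1]^2, cent[, 2] / axes[2]^2,
                               cent[, 3] / axes[3]^2))
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(e_t)), ncol = 3)
  e_l <- zhat - e_t * e_t[, 3]
  nl <- sqrt(rowSums(e_l^2))
  bad <- nl < 1e-8   # should not happen away from the poles
  if (any(bad)) {
    e_l[bad, ] <- matrix(rep(c(1, 0, 0), each = sum(bad)), ncol = 3) -
      e_t[bad, , drop = FALSE] * e_t[bad, 1]
  }
  e_l <- .normalise_rows(e_l)
  e_c <- .row_cross(e_l, e_t)   # unit: e_l and e_t are orthonormal
  mesh$element_centroid <- cent
  mesh$axis_circ <- e_c
  mesh$axis_long <- e_l
  mesh$axis_trans <- e_t
  mesh$element_transmural <- (mesh$transmural[mesh$elements[, 1]] +
                              mesh$transmural[mesh$elements[, 2]] +
                              mesh$transmural[mesh$elements[, 3]] +
                              mesh$transmural[mesh$elements[, 4]]) / 4
  mesh
}

#' Assign rule-based fibre/sheet/sheet-normal frames
#'
#' The fibre helix angle varies linearly with wall depth,
#' `alpha(d) = endo_angle + d * (epi_angle - endo_angle)` with `d` the
#' element-mean transmural coordinate, the standard rule-based model for
#' ventricular myofibre architecture.  The fibre vector lies in the local
#' circumferential--longitudinal plane rotated by `alpha` about the
#' transmural axis, the sheet vector is transmural, and the sheet-normal
#' completes a right-handed orthonormal triple.
#'
#' @param mesh a `bivmesh` (must carry transmural coordinates).
#' @param endo_angle_deg helix angle at the endocardium (degrees).
#' @param epi_angle_deg helix angle at the epicardium (degrees).
#' @return the mesh with `fibre`, `sheet`, `normal` (element x 3 matrices)
#'   and `element_helix_deg` filled in.
#' @export
assign_fibre_frames <- function(mesh, endo_angle_deg = 60, epi_angle_deg = -60) {
  stopifnot(inherits(mesh, "bivmesh"))
  if (is.null(mesh$transmural) || anyNA(mesh$transmural))
    stop("mesh has no transmural coordinates; cannot assign fibre frames")
  if (is.null(mesh$axis_circ)) mesh <- .element_local_axes(mesh)
  d <- mesh$element_transmural
  alpha <- (endo_angle_deg + d * (epi_angle_deg - endo_angle_deg)) * pi / 180
  f <- mesh$axis_circ * cos(alpha) + mesh$axis_long * sin(alpha)
  s <- mesh$axis_trans
  n <- .row_cross(f, s)
  mesh$fibre <- f
  mesh$sheet <- s
  mesh$normal <- n
  mesh$element_helix_deg <- alpha * 180 / pi
  mesh$fibre_angles <- c(endo = endo_angle_deg, epi = epi_angle_deg)
  mesh
}

#' @export
print.bivmesh <- function(x, ...) {
  cat("Synthetic biventricular mesh\n")
  cat(sprintf("  nodes: %d   tetrahedra: %d\n", nrow(x$nodes), nrow(x$elements)))
  cat(sprintf("  myocardial volume: %.1f cm^3\n", x$volume_cm3))
  tab <- table(factor(x$surface, levels = SURFACE_LEVELS))
  cat(sprintf("  surface nodes: LV_ENDO %d, RV_ENDO %d, EPI %d, interior %d\n",
              tab[["LV_ENDO"]], tab[["RV_ENDO"]], tab[["EPI"]], tab[["INTERIOR"]]))
  invisible(x)
}

#' Validate the structural invariants of a biventricular mesh
#'
#' Checks frame orthonormality, transmural-coordinate anchoring on the
#' labelled surfaces, non-empty surface label sets and positive element
#' volumes.  Called by tests and by I/O round trips.
#'
#' @param mesh a `bivmesh`.
#' @param tol tolerance for frame orthonormality.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  stopifnot(inherits(mesh, "bivmesh"))
  for (lbl in c("LV_ENDO", "RV_ENDO", "EPI"))
    if (!any(mesh$surface == lbl)) stop("empty surface label set: ", lbl)
  if (any(.tet_volumes(mesh$nodes, mesh$elements) <= 0))
    stop("non-positive element volumes")
  f <- mesh$fibre; s <- mesh$sheet; n <- mesh$normal
  if (max(abs(rowSums(f^2) - 1)) > tol || max(abs(rowSums(s^2) - 1)) > tol ||
      max(abs(rowSums(n^2) - 1)) > tol)
    stop("element frames are not unit length")
  if (max(abs(rowSums(f * s))) > tol || max(abs(rowSums(f * n))) > tol ||
      max(abs(rowSums(s * n))) > tol)
    stop("element frames are not orthogonal")
  endo <- mesh$surface %in% c("LV_ENDO", "RV_ENDO")
  if (any(mesh$transmural[endo] != 0)) stop("transmural != 0 on endocardium")
  if (any(mesh$transmural[mesh$surface == "EPI"] != 1))
    stop("transmural != 1 on epicardium")
  invisible(TRUE)
}

#' Discretise candidate root-node locations on the endocardial surfaces
#'
#' Candidate earliest-activation sites are chosen by greedy farthest-point
#' sampling on each endocardial surface until every endocardial node lies
#' within the coverage radius of a same-ventricle candidate: 2.5 cm at low
#' resolution, 1.5 cm at high resolution, and the hybrid resolution combines
#' the low-resolution right-ventricular set with the high-resolution
#' left-ventricular set.  Sampling starts at the node nearest each
#' ventricle's endocardial centroid and is fully deterministic (ties broken
#' by node index).
#'
#' @param mesh a `bivmesh`.
#' @param resolution `"LOW"`, `"HIGH"` or `"HYBRID"`.
#' @return object of class `root_candidates` with fields `node_id` (1-based
#'   mesh node indices), `ventricle`, `resolution` and `coverage_cm` (the
#'   realised worst-case distance per ventricle).
#' @export
discretise_root_candidates <- function(mesh, resolution = c("LOW", "HIGH", "HYBRID")) {
  stopifnot(inherits(mesh, "bivmesh"))
  resolution <- match.arg(resolution)
  radius_for <- function(vent) {
    switch(resolution,
           LOW = 2.5, HIGH = 1.5,
           HYBRID = if (vent == "LV") 1.5 else 2.5)
  }
  out_id <- integer(0); out_vent <- character(0); cov <- c(LV = NA_real_, RV = NA_real_)
  for (vent in c("LV", "RV")) {
    nodes_v <- which(!is.na(mesh$ventricle) & mesh$ventricle == vent)
    if (length(nodes_v) == 0) stop("empty endocardial surface for ", vent)
    pts <- mesh$nodes[nodes_v, , drop = FALSE]
    sel <- .farthest_point_sample(pts, radius_for(vent))
    out_id <- c(out_id, nodes_v[sel$picked])
    out_vent <- c(out_vent, rep(vent, length(sel$picked)))
    cov[[vent]] <- sel$coverage
  }
  structure(list(node_id = out_id, ventricle = out_vent,
                 resolution = resolution, coverage_cm = cov),
            class = "root_candidates")
}

# greedy farthest-point sampling with a coverage-radius stopping rule
.farthest_point_sample <- function(pts, radius) {
  n <- nrow(pts)
  centroid <- colMeans(pts)
  d0 <- sqrt(colSums((t(pts) - centroid)^2))
  start <- which(d0 == min(d0))[1L]
  picked <- start
  mind <- sqrt(rowSums((pts - matrix(pts[start, ], n, 3, byrow = TRUE))^2))
  while (max(mind) > radius) {
    nxt <- which(mind == max(mind))[1L]
    picked <- c(picked, nxt)
    dn <- sqrt(rowSums((pts - matrix(pts[nxt, ], n, 3, byrow = TRUE))^2))
    mind <- pmin(mind, dn)
  }
  list(picked = picked, coverage = max(mind))
}

#' @export
print.root_candidates <- function(x, ...) {
  cat(sprintf("Root-node candidates (%s resolution): %d total (LV %d, RV %d)\n",
              x$resolution, length(x$node_id), sum(x$ventricle == "LV"),
              sum(x$ventricle == "RV")))
  cat(sprintf("  realised coverage: LV %.2f cm, RV %.2f cm\n",
              x$coverage_cm[["LV"]], x$coverage_cm[["RV"]]))
  invisible(x)
}

#' Maximum endocardium-to-candidate coverage distance
#'
#' For every endocardial node, the Euclidean distance to the nearest
#' same-ventricle candidate; returns the maximum (the realised coverage
#' radius of the discretisation).
#'
#' @param mesh a `bivmesh`.
#' @param candidates a `root_candidates` object.
#' @return named numeric: per-ventricle and overall maximum distance (cm).
#' @export
candidate_coverage <- function(mesh, candidates) {
  out <- c(LV = NA_real_, RV = NA_real_)
  for (vent in c("LV", "RV")) {
    nodes_v <- which(!is.na(mesh$ventricle) & mesh$ventricle == vent)
    cand_v <- candidates$node_id[candidates$ventricle == vent]
    d <- .min_dist_to_set(mesh$nodes[nodes_v, , drop = FALSE],
                          mesh$nodes[cand_v, , drop = FALSE])
    out[[vent]] <- max(d)
  }
  c(out, overall = max(out))
}

#' Place the 10 standard ECG electrodes around the heart
#'
#' Electrodes are placed at anatomical proportions of a torso bounding box
#' enclosing the heart: the four limb electrodes at the box corners and the
#' six precordial electrodes V1--V6 on a left-anterior arc (+x is the
#' anterior direction, +y the subject's left).  Placement is deterministic
#' and scales linearly with the torso box.
#'
#' @param mesh a `bivmesh`.
#' @param torso_scale half-width of the torso box relative to the heart's
#'   bounding half-width (must exceed 1.15 so electrodes stay clear of the
#'   myocardium).
#' @return object of class `electrode_set`: a data.frame `name,x,y,z` (cm).
#' @export
place_electrodes <- function(mesh, torso_scale = 1.6) {
  stopifnot(inherits(mesh, "bivmesh"))
  if (torso_scale <= 1.15) stop("`torso_scale` must exceed 1.15")
  lo <- apply(mesh$nodes, 2, min); hi <- apply(mesh$nodes, 2, max)
  ctr <- (lo + hi) / 2
  s <- torso_scale * (hi - lo) / 2
  P <- function(fx, fy, fz) c(ctr[1] + fx * s[1], ctr[2] + fy * s[2],
                              ctr[3] + fz * s[3])
  pos <- rbind(
    RA = P(0.0, -1.0,  1.0),
    LA = P(0.0,  1.0,  1.0),
    LL = P(0.0,  1.0, -1.0),
    RL = P(0.0, -1.0, -1.0),
    V1 = P(1.0, -0.15, 0.15),
    V2 = P(1.0,  0.15, 0.15),
    V3 = P(1.0,  0.40, 0.00),
    V4 = P(1.0,  0.60, -0.10),
    V5 = P(0.95, 0.80, -0.10),
    V6 = P(0.90, 1.00, -0.10))
  df <- data.frame(name = rownames(pos), x = pos[, 1], y = pos[, 2],
                   z = pos[, 3], row.names = NULL,
                   stringsAsFactors = FALSE)
  # every electrode must be strictly outside the myocardial point cloud
  dmin <- .min_dist_to_set(as.matrix(df[, c("x", "y", "z")]), mesh$nodes)
  if (any(dmin <= mesh$anatomy$edge_length))
    stop("electrode placement too close to the myocardium")
  structure(df, class = c("electrode_set", "data.frame"))
}
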