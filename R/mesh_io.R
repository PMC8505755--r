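# File formats.  Node indices are 0-based in every on-disk format (VTK and
# CSV alike) and converted to R's 1-based indexing on load.

#' Write a biventricular mesh as a legacy ASCII VTK unstructured grid
#'
#' Point data: `surface_label` (integer code: 0 INTERIOR, 1 LV_ENDO,
#' 2 RV_ENDO, 3 EPI) and `transmural`; cell data: `fibre`, `sheet`,
#' `normal` vectors.
#'
#' @param mesh a `bivmesh`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "bivmesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioinfer biventricular mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", e, 5L * e), con)
  cells <- cbind(4L, mesh$elements - 1L)
  writeLines(apply(cells, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(as.character(rep(10L, e)), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS surface_label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$surface, SURFACE_LEVELS) - 1L), con)
  writeLines(c("SCALARS transmural double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh$transmural, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  writeLines(sprintf("CELL_DATA %d", e), con)
  for (fld in c("fibre", "sheet", "normal")) {
    writeLines(sprintf("VECTORS %s double", fld), con)
    writeLines(apply(format(mesh[[fld]], digits = 17, trim = TRUE,
                            scientific = FALSE), 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' A minimal legacy-VTK reader for the subset this package writes
#' (tetrahedral unstructured grid with the package's point/cell data).
#' Transmural coordinates, local axes and the helix-angle fields are
#' reconstructed from the loaded geometry.
#'
#' @param path file path.
#' @param anatomy optional anatomy parameter list to attach (used for the
#'   local frame axes; defaults to a bounding-box estimate).
#' @return a `bivmesh`.
#' @export
read_mesh_vtk <- function(path, anatomy = NULL) {
  lines <- readLines(path)
  find <- function(pat) grep(pat, lines)[1]
  ip <- find("^POINTS ")
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- find("^CELLS ")
  e <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- matrix(as.integer(scan(text = lines[(ic + 1):(ic + e)],
                                  quiet = TRUE)), ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4L)) stop("only tetrahedral cells are supported")
  elements <- cells[, 2:5, drop = FALSE] + 1L
  is_ <- find("^SCALARS surface_label")
  surface <- SURFACE_LEVELS[as.integer(lines[(is_ + 2):(is_ + 1 + n)]) + 1L]
  it <- find("^SCALARS transmural")
  transmural <- as.numeric(lines[(it + 2):(it + 1 + n)])
  vec <- function(name) {
    iv <- find(paste0("^VECTORS ", name))
    matrix(scan(text = lines[(iv + 1):(iv + e)], quiet = TRUE),
           ncol = 3, byrow = TRUE)
  }
  ventricle <- rep(NA_character_, n)
  ventricle[surface == "LV_ENDO"] <- "LV"
  ventricle[surface == "RV_ENDO"] <- "RV"
  if (is.null(anatomy)) {
    hw <- (apply(nodes, 2, max) - apply(nodes, 2, min)) / 2
    anatomy <- list(axes = hw, wall_thickness = NA_real_, edge_length = 0.5)
  }
  vol <- abs(.tet_volumes(nodes, elements))
  mesh <- structure(list(nodes = nodes, elements = elements, surface = surface,
                         ventricle = ventricle, transmural = transmural,
                         element_volume = vol, volume_cm3 = sum(vol),
                         anatomy = anatomy), class = "bivmesh")
  mesh <- .element_local_axes(mesh)
  mesh$fibre <- vec("fibre")
  mesh$sheet <- vec("sheet")
  mesh$normal <- vec("normal")
  mesh
}

#' Write / read a mesh as a CSV triplet
#'
#' `nodes.csv` (`x,y,z`), `elements.csv` (0-based `n1..n4`), `labels.csv`
#' (`node_id,surface_label,transmural,ventricle`), all inside `dir`.
#'
#' @param mesh a `bivmesh`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                       z = mesh$nodes[, 3]),
            file.path(dir, "nodes.csv"), row.names = FALSE)
  el <- as.data.frame(mesh$elements - 1L)
  names(el) <- paste0("n", 1:4)
  write.csv(el, file.path(dir, "elements.csv"), row.names = FALSE)
  write.csv(data.frame(node_id = seq_len(nrow(mesh$nodes)) - 1L,
                       surface_label = mesh$surface,
                       transmural = mesh$transmural,
                       ventricle = ifelse(is.na(mesh$ventricle), "",
                                          mesh$ventricle)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mesh_csv
#' @param anatomy optional anatomy list, as for [read_mesh_vtk()].
#' @export
read_mesh_csv <- function(dir, anatomy = NULL) {
  nodes <- as.matrix(read.csv(file.path(dir, "nodes.csv")))
  dimnames(nodes) <- NULL
  elements <- as.matrix(read.csv(file.path(dir, "elements.csv"))) + 1L
  dimnames(elements) <- NULL
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  lab <- lab[order(lab$node_id), ]
  ventricle <- lab$ventricle
  ventricle[ventricle == ""] <- NA_character_
  if (is.null(anatomy)) {
    hw <- (apply(nodes, 2, max) - apply(nodes, 2, min)) / 2
    anatomy <- list(axes = hw, wall_thickness = NA_real_, edge_length = 0.5)
  }
  vol <- abs(.tet_volumes(nodes, elements))
  mesh <- structure(list(nodes = nodes, elements = elements,
                         surface = lab$surface_label, ventricle = ventricle,
                         transmural = lab$transmural, element_volume = vol,
                         volume_cm3 = sum(vol), anatomy = anatomy),
                    class = "bivmesh")
  mesh <- .element_local_axes(mesh)
  assign_fibre_frames(mesh)
}

#' Electrode, candidate and activation-map CSV I/O
#'
#' Electrodes: `name,x,y,z`.  Candidates: `candidate_id,node_id,ventricle`
#' (0-based ids).  Activation maps: `node_id,activation_time_ms` (0-based).
#'
#' @param x object to write.
#' @param path file path.
#' @return the written path / the loaded object.
#' @export
write_electrodes_csv <- function(x, path) {
  stopifnot(inherits(x, "electrode_set"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_csv
#' @export
read_electrodes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(sort(df$name),
                      sort(c("RA", "LA", "LL", "RL", paste0("V", 1:6)))))
  structure(df, class = c("electrode_set", "data.frame"))
}

#' @rdname write_electrodes_csv
#' @export
write_candidates_csv <- function(x, path) {
  stopifnot(inherits(x, "root_candidates"))
  write.csv(data.frame(candidate_id = seq_along(x$node_id) - 1L,
                       node_id = x$node_id - 1L,
                       ventricle = x$ventricle),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_csv
#' @param resolution resolution tag to attach on load.
#' @export
read_candidates_csv <- function(path, resolution = "LOW") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$candidate_id), ]
  structure(list(node_id = df$node_id + 1L, ventricle = df$ventricle,
                 resolution = resolution,
                 coverage_cm = c(LV = NA_real_, RV = NA_real_)),
            class = "root_candidates")
}

#' @rdname write_electrodes_csv
#' @export
write_atm_csv <- function(x, path) {
  stopifnot(inherits(x, "activation_map"))
  write.csv(data.frame(node_id = x$node_id - 1L,
                       activation_time_ms = x$time_ms),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_csv
#' @export
read_atm_csv <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$node_id), ]
  structure(list(node_id = df$node_id + 1L, time_ms = df$activation_time_ms),
            class = "activation_map")
}

#' @rdname write_electrodes_csv
#' @export
write_qrs_csv <- function(x, path) {
  stopifnot(inherits(x, "qrs_recording"))
  df <- data.frame(time_ms = x$time_ms)
  df[LEAD_NAMES] <- as.data.frame(x$leads)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_csv
#' @export
read_qrs_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  leads <- as.matrix(df[, LEAD_NAMES])
  structure(list(time_ms = df$time_ms, leads = leads,
                 duration_ms = if (nrow(df) > 1)
                   df$time_ms[nrow(df)] - df$time_ms[1] else 0),
            class = "qrs_recording")
}
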