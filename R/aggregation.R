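# Collapse a final population into a single solution (median speeds,
# k-means root-node centroids) and compute evaluation metrics against a
# known ground truth.

#' Aggregate conduction speeds as component-wise population medians
#'
#' Medians of ordered tuples preserve the fibre >= sheet >= sheet-normal
#' ordering, so the result is itself a valid speed set.
#'
#' @param pop a `population`.
#' @return a `conduction_speeds`.
#' @export
aggregate_speeds <- function(pop) {
  if (length(pop$members) == 0) stop("empty population")
  sp <- vapply(pop$members, function(m) unclass(m$speeds), numeric(4))
  med <- apply(sp, 1, median)
  conduction_speeds(med[1], med[2], med[3], med[4])
}

# Lloyd iterations from given centroids; stops when assignments stabilise.
# The within-cluster sum of squares is checked to be non-increasing.
.lloyd <- function(points, centroids, max_iter = 300) {
  assign_pts <- function(cent) {
    d2 <- outer(rowSums(points^2), rowSums(cent^2), "+") -
      2 * points %*% t(cent)
    max.col(-d2, ties.method = "first")
  }
  wcss <- function(cent, asg) {
    sum((points - cent[asg, , drop = FALSE])^2)
  }
  asg <- assign_pts(centroids)
  obj <- wcss(centroids, asg)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(nrow(centroids))) {
      in_k <- asg == k
      if (any(in_k))
        centroids[k, ] <- colMeans(points[in_k, , drop = FALSE])
    }
    new_asg <- assign_pts(centroids)
    new_obj <- wcss(centroids, new_asg)
    if (new_obj > obj + 1e-9) stop("k-means objective increased")
    obj <- new_obj
    if (identical(new_asg, asg)) break
    asg <- new_asg
  }
  list(centroids = centroids, assignment = asg, wcss = obj)
}

#' Aggregate root nodes as k-means centroids of the pooled population
#'
#' The 3-D coordinates of every active root node across all members are
#' pooled; k is the active-root count of the modal (most frequently
#' occurring) root configuration and the initial centroids are that
#' configuration's coordinates, which guarantees a spread-out,
#' representative initialisation.  When every configuration is unique, k is
#' the modal root-node cardinality and the initialisation comes from the
#' lowest-discrepancy member.  Centroids are tagged with the ventricle of
#' the nearest endocardial node.
#'
#' @param pop a `population`.
#' @param candidates the `root_candidates` the members are defined over.
#' @param mesh the `bivmesh`.
#' @return object of class `aggregated_roots`: `centroids` (k x 3),
#'   `ventricle`, `k`, `wcss`.
#' @export
aggregate_root_nodes <- function(pop, candidates, mesh) {
  if (length(pop$members) == 0) stop("empty population")
  coords <- mesh$nodes[candidates$node_id, , drop = FALSE]
  masks <- vapply(pop$members, function(m)
    paste(as.integer(m$root_active), collapse = ""), character(1))
  pooled <- do.call(rbind, lapply(pop$members, function(m)
    coords[m$root_active, , drop = FALSE]))

  tab <- table(masks)
  if (max(tab) > 1) {
    modal_mask <- names(tab)[which.max(tab)]       # ties: first = stable
    modal_active <- as.integer(strsplit(modal_mask, "")[[1]]) == 1L
    init <- coords[modal_active, , drop = FALSE]
  } else {
    counts <- vapply(pop$members, function(m) sum(m$root_active), integer(1))
    ctab <- table(counts)
    k <- as.integer(names(ctab)[which.max(ctab)])
    best <- which.min(pop$discrepancy)
    best_coords <- coords[pop$members[[best]]$root_active, , drop = FALSE]
    init <- best_coords[seq_len(min(k, nrow(best_coords))), , drop = FALSE]
    message("all root configurations unique; initialising k-means from the ",
            "lowest-discrepancy member (k = ", nrow(init), ")")
  }
  fit <- .lloyd(pooled, init)

  endo_idx <- which(!is.na(mesh$ventricle))
  endo_pts <- mesh$nodes[endo_idx, , drop = FALSE]
  vent <- vapply(seq_len(nrow(fit$centroids)), function(i) {
    d2 <- rowSums((endo_pts - matrix(fit$centroids[i, ], nrow(endo_pts), 3,
                                     byrow = TRUE))^2)
    mesh$ventricle[endo_idx[which.min(d2)]]
  }, character(1))
  structure(list(centroids = fit$centroids, ventricle = vent,
                 k = nrow(fit$centroids), wcss = fit$wcss),
            class = "aggregated_roots")
}

#' Signed percentage error of an inferred conduction speed
#'
#' `100 * (inferred - truth) / truth`; summaries report the absolute value.
#'
#' @param inferred,truth speeds in cm/s (vectorised; truth must be > 0).
#' @return signed percentage error.
#' @export
speed_error_percent <- function(inferred, truth) {
  if (any(truth <= 0)) stop("ground-truth speed must be positive")
  100 * (inferred - truth) / truth
}

#' Root-node recovery errors per ventricle
#'
#' For each true root node, the Euclidean distance to the nearest inferred
#' centroid of the same ventricle, plus the absolute error in the number of
#' root nodes, reported per ventricle.
#'
#' @param roots an `aggregated_roots` (or a k x 3 matrix with a `ventricle`
#'   attribute vector).
#' @param true_coords matrix of true root-node positions (n x 3).
#' @param true_ventricle character vector (`"LV"`/`"RV"`) per true root.
#' @return data.frame with one row per ventricle: `mean_distance_cm`,
#'   `sd_distance_cm`, `count_error`.
#' @export
root_node_errors <- function(roots, true_coords, true_ventricle) {
  if (nrow(true_coords) == 0) stop("no true root nodes supplied")
  cent <- if (inherits(roots, "aggregated_roots")) roots$centroids else roots
  cvent <- if (inherits(roots, "aggregated_roots")) roots$ventricle
           else attr(roots, "ventricle")
  out <- lapply(c("LV", "RV"), function(v) {
    tr <- true_coords[true_ventricle == v, , drop = FALSE]
    ce <- cent[cvent == v, , drop = FALSE]
    if (nrow(tr) == 0)
      return(data.frame(ventricle = v, mean_distance_cm = NA_real_,
                        sd_distance_cm = NA_real_,
                        count_error = nrow(ce)))
    if (nrow(ce) == 0)
      return(data.frame(ventricle = v, mean_distance_cm = Inf,
                        sd_distance_cm = NA_real_, count_error = nrow(tr)))
    d <- vapply(seq_len(nrow(tr)), function(i) {
      min(sqrt(rowSums((ce - matrix(tr[i, ], nrow(ce), 3, byrow = TRUE))^2)))
    }, numeric(1))
    data.frame(ventricle = v, mean_distance_cm = mean(d),
               sd_distance_cm = if (length(d) > 1) sd(d) else 0,
               count_error = abs(nrow(ce) - nrow(tr)))
  })
  do.call(rbind, out)
}

#' Pearson correlation between predicted and target data
#'
#' For the ATM modality, the product-moment correlation over the epicardial
#' nodes; for the ECG modality, the correlation is computed per lead on the
#' overlapping samples and averaged.
#'
#' @param predicted,target numeric vectors, `activation_map`s, or
#'   `qrs_recording`s.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(predicted, target) {
  if (inherits(predicted, "qrs_recording") &&
      inherits(target, "qrs_recording")) {
    n <- min(nrow(predicted$leads), nrow(target$leads))
    rs <- vapply(LEAD_NAMES, function(ld) {
      a <- predicted$leads[seq_len(n), ld]
      b <- target$leads[seq_len(n), ld]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    return(mean(rs, na.rm = TRUE))
  }
  p <- if (inherits(predicted, "activation_map")) predicted$time_ms
       else as.numeric(predicted)
  t_ <- if (inherits(target, "activation_map")) target$time_ms
        else as.numeric(target)
  if (length(p) != length(t_)) stop("length mismatch")
  if (length(p) < 3) stop("need at least 3 samples")
  if (sd(p) == 0 || sd(t_) == 0) stop("zero variance input")
  cor(p, t_)
}

#' Evaluation report for one inference run
#'
#' Combines the aggregated solution with the ground truth: signed and
#' absolute speed errors, per-ventricle root-node distance/count errors and
#' the Pearson correlation between the aggregated prediction and the
#' target.
#'
#' @param pop final `population`.
#' @param candidates,mesh as used by the inference.
#' @param truth list with `speeds` (`conduction_speeds`) and `root_node_ids`
#'   (1-based mesh node indices of the true roots).
#' @param target,modality optional target data for the correlation entry.
#' @param forward optional forward closure to evaluate the aggregated
#'   solution.
#' @return object of class `evaluation_report` (a list; see fields).
#' @export
evaluation_report <- function(pop, candidates, mesh, truth,
                              target = NULL, modality = "ATM",
                              forward = NULL) {
  sp <- aggregate_speeds(pop)
  roots <- aggregate_root_nodes(pop, candidates, mesh)
  err <- speed_error_percent(unclass(sp), unclass(truth$speeds))
  true_coords <- mesh$nodes[truth$root_node_ids, , drop = FALSE]
  true_vent <- mesh$ventricle[truth$root_node_ids]
  rerr <- root_node_errors(roots, true_coords, true_vent)
  r <- NA_real_
  if (!is.null(target) && !is.null(forward)) {
    agg_member <- parameter_set(sp, .nearest_candidate_mask(
      roots, candidates, mesh))
    pred <- tryCatch(forward(agg_member), error = function(e) NULL)
    if (!is.null(pred)) r <- pearson_correlation(pred, target)
  }
  structure(list(speeds = sp,
                 speed_error_percent = err,
                 speed_abs_error_percent = abs(err),
                 roots = roots,
                 root_errors = rerr,
                 pearson = r),
            class = "evaluation_report")
}

# express aggregated centroids as the nearest candidate subset (clamped to
# the root-count range) so the aggregated solution can be simulated
.nearest_candidate_mask <- function(roots, candidates, mesh) {
  coords <- mesh$nodes[candidates$node_id, , drop = FALSE]
  picked <- unique(vapply(seq_len(nrow(roots$centroids)), function(i) {
    d2 <- rowSums((coords - matrix(roots$centroids[i, ], nrow(coords), 3,
                                   byrow = TRUE))^2)
    which.min(d2)
  }, integer(1)))
  k <- length(picked)
  if (k < ROOT_COUNT_RANGE[1]) {
    extra <- setdiff(seq_len(nrow(coords)), picked)
    picked <- c(picked, extra[seq_len(ROOT_COUNT_RANGE[1] - k)])
  } else if (k > ROOT_COUNT_RANGE[2]) {
    picked <- picked[seq_len(ROOT_COUNT_RANGE[2])]
  }
  mask <- rep(FALSE, nrow(coords))
  mask[picked] <- TRUE
  mask
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat("  aggregated speeds (cm/s): ",
      paste(sprintf("%s=%.1f", names(x$speeds), unclass(x$speeds)),
            collapse = ", "), "\n", sep = "")
  cat("  speed errors (%): ",
      paste(sprintf("%s=%+.1f", names(x$speed_error_percent),
                    x$speed_error_percent), collapse = ", "), "\n", sep = "")
  print(x$root_errors, row.names = FALSE)
  if (!is.na(x$pearson))
    cat(sprintf("  Pearson correlation with target: %.3f\n", x$pearson))
  invisible(x)
}

#' Write an evaluation report as JSON (plus centroid CSV)
#'
#' @param report an `evaluation_report`.
#' @param path JSON output path; centroids go to `<path>_centroids.csv`.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    speeds = as.list(unclass(report$speeds)),
    speed_error_percent = as.list(report$speed_error_percent),
    speed_abs_error_percent = as.list(report$speed_abs_error_percent),
    root_errors = report$root_errors,
    pearson = report$pearson)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  cent <- data.frame(x = report$roots$centroids[, 1],
                     y = report$roots$centroids[, 2],
                     z = report$roots$centroids[, 3],
                     ventricle = report$roots$ventricle)
  write.csv(cent, paste0(sub("\\.json$", "", path), "_centroids.csv"),
            row.names = FALSE)
  invisible(path)
}
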