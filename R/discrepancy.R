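# Prediction--target discrepancies: RMSE for epicardial activation maps,
# constrained DTW + QRS-width penalty for 12-lead QRS recordings.

#' Configuration for the constrained DTW discrepancy
#'
#' The alignment is a monotone path with common start and end.  The
#' warping-slope constraint forbids more than two consecutive off-diagonal
#' steps in the same direction, so one sample aligns to at most three of the
#' other series.  Off-diagonal steps pay an additive penalty that decays
#' linearly along the path from `start_penalty_weight` to
#' `end_penalty_weight` (warping is cheapest near the end of the QRS, where
#' activation-sequence differences accumulate).  The parallelogram band is
#' tight at the start (`band_start_halfwidth` samples) and opens linearly to
#' `band_end_fraction` of the target length.  A `width_penalty_weight`-
#' weighted absolute QRS-width difference is added on top of the mean lead
#' cost.
#'
#' @param start_penalty_weight off-diagonal penalty at the path start; `NULL`
#'   means 0.2 x the target lead's amplitude range, resolved per lead.
#' @param end_penalty_weight off-diagonal penalty at the path end.
#' @param width_penalty_weight weight (per ms) of the QRS-width penalty.
#' @param band_start_halfwidth band half-width at the start, in samples.
#' @param band_end_fraction band half-width at the end, as a fraction of the
#'   target length.
#' @return object of class `dtw_config`.
#' @export
dtw_config <- function(start_penalty_weight = NULL,
                       end_penalty_weight = 0,
                       width_penalty_weight = 0.05,
                       band_start_halfwidth = 2,
                       band_end_fraction = 0.25) {
  if (!is.null(start_penalty_weight) &&
      start_penalty_weight < end_penalty_weight)
    stop("need start_penalty_weight >= end_penalty_weight")
  if (end_penalty_weight < 0 || width_penalty_weight < 0)
    stop("penalty weights must be non-negative")
  structure(list(start_penalty_weight = start_penalty_weight,
                 end_penalty_weight = end_penalty_weight,
                 width_penalty_weight = width_penalty_weight,
                 band_start_halfwidth = band_start_halfwidth,
                 band_end_fraction = band_end_fraction,
                 max_consecutive_warps = 2L),
            class = "dtw_config")
}

#' Parallelogram band mask for the constrained DTW
#'
#' Cell (i, j) is admissible when the deviation from the diagonal (in
#' samples of the target series) does not exceed the half-width, which
#' grows linearly with path progress from `band_start_halfwidth` to
#' `band_end_fraction * m`.  Degenerate series (length 1) admit everything;
#' the slope constraint still applies.  Exported so that independent
#' brute-force checks can share the problem definition.
#'
#' @param n,m series lengths.
#' @param cfg a `dtw_config`.
#' @return an `n x m` logical matrix.
#' @export
dtw_band_mask <- function(n, m, cfg = dtw_config()) {
  if (n == 1 || m == 1) return(matrix(TRUE, n, m))
  pi_ <- (seq_len(n) - 1) / (n - 1)
  pj_ <- (seq_len(m) - 1) / (m - 1)
  dev <- abs(outer(pi_, pj_, "-")) * (m - 1)
  p <- (outer(pi_, pj_, "+")) / 2
  halfwidth <- cfg$band_start_halfwidth +
    p * (cfg$band_end_fraction * m - cfg$band_start_halfwidth)
  mask <- dev <= halfwidth
  mask[1, 1] <- TRUE
  mask[n, m] <- TRUE
  mask
}

#' RMSE discrepancy between two epicardial activation maps
#'
#' @param predicted,target `activation_map`s restricted to the same node set
#'   and ordering (or plain numeric vectors).
#' @return discrepancy in ms (class `discrepancy_value`, modality `"ATM"`).
#' @export
atm_rmse <- function(predicted, target) {
  p <- if (inherits(predicted, "activation_map")) predicted$time_ms else predicted
  t_ <- if (inherits(target, "activation_map")) target$time_ms else target
  if (length(p) != length(t_))
    stop("activation maps have different lengths (", length(p), " vs ",
         length(t_), ")")
  if (inherits(predicted, "activation_map") &&
      inherits(target, "activation_map") &&
      !identical(predicted$node_id, target$node_id))
    stop("activation maps cover different node sets")
  structure(sqrt(mean((p - t_)^2)), modality = "ATM",
            class = "discrepancy_value")
}

#' Constrained DTW alignment of two single-lead series
#'
#' Dynamic programme over monotone paths from the first to the last sample
#' pair, with local cost `|a_i - b_j|`, the warping-slope constraint, the
#' linearly decaying off-diagonal penalty and the parallelogram band of
#' `cfg` (see [dtw_config()]).  The returned cost is the optimal total
#' accumulated cost divided by the optimal path's length.
#'
#' @param a,b numeric series (non-empty).
#' @param cfg a `dtw_config`.
#' @return list with `cost` (normalised), `total_cost`, `path` (two-column
#'   matrix of 1-based indices), `feasible`.  When no admissible path
#'   exists, `feasible` is `FALSE` and `cost` is the largest finite value.
#' @export
constrained_dtw <- function(a, b, cfg = dtw_config()) {
  if (length(a) < 1 || length(b) < 1) stop("series must be non-empty")
  start_w <- cfg$start_penalty_weight
  if (is.null(start_w)) start_w <- 0.2 * diff(range(b))
  mask <- dtw_band_mask(length(a), length(b), cfg)
  res <- .dtw_core_cpp(as.numeric(a), as.numeric(b), mask,
                       start_w, cfg$end_penalty_weight)
  if (!res$feasible) {
    return(list(cost = .Machine$double.xmax, total_cost = NA_real_,
                path = NULL, feasible = FALSE))
  }
  list(cost = res$total_cost / nrow(res$path),
       total_cost = res$total_cost,
       path = res$path,
       feasible = TRUE)
}

#' QRS-width penalty
#'
#' @param a,b `qrs_recording`s (or numeric durations in ms).
#' @param weight non-negative weight.
#' @return `weight * |duration(a) - duration(b)|`.
#' @export
qrs_width_penalty <- function(a, b, weight = 0.05) {
  da <- if (inherits(a, "qrs_recording")) a$duration_ms else as.numeric(a)
  db <- if (inherits(b, "qrs_recording")) b$duration_ms else as.numeric(b)
  weight * abs(da - db)
}

#' ECG discrepancy: mean constrained-DTW cost over the independent leads
#' plus the QRS-width penalty
#'
#' Only the eight linearly independent leads (I, II, V1--V6) enter the mean;
#' III and the augmented leads are linear combinations and would double
#' count.  An infeasible alignment in any lead makes the whole discrepancy
#' infeasible (sentinel value).
#'
#' @param predicted,target `qrs_recording`s.
#' @param cfg a `dtw_config`.
#' @return scalar of class `discrepancy_value` (modality `"ECG"`) with a
#'   `per_lead` attribute.
#' @export
ecg_discrepancy <- function(predicted, target, cfg = dtw_config()) {
  stopifnot(inherits(predicted, "qrs_recording"),
            inherits(target, "qrs_recording"))
  if (!all(INDEPENDENT_LEADS %in% colnames(predicted$leads)) ||
      !all(INDEPENDENT_LEADS %in% colnames(target$leads)))
    stop("lead sets do not match the 12-lead standard")
  per_lead <- vapply(INDEPENDENT_LEADS, function(ld) {
    r <- constrained_dtw(predicted$leads[, ld], target$leads[, ld], cfg)
    if (!r$feasible) return(NA_real_)
    r$cost
  }, numeric(1))
  if (anyNA(per_lead)) {
    return(structure(.Machine$double.xmax, modality = "ECG",
                     per_lead = per_lead, feasible = FALSE,
                     class = "discrepancy_value"))
  }
  val <- mean(per_lead) +
    qrs_width_penalty(predicted, target, cfg$width_penalty_weight)
  structure(val, modality = "ECG", per_lead = per_lead, feasible = TRUE,
            class = "discrepancy_value")
}

#' @export
print.discrepancy_value <- function(x, ...) {
  cat(sprintf("%s discrepancy: %.6g\n", attr(x, "modality"), unclass(x)))
  invisible(x)
}
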