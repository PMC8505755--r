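# Pseudo-ECG: extracellular potential surrogate computed as the volume sum
# of transmembrane-potential gradients dotted with the gradient of 1/r to
# each electrode, in an infinite homogeneous volume conductor.

LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
MEASURE_ELECTRODES <- c("RA", "LA", "LL", paste0("V", 1:6))
INDEPENDENT_LEADS <- c("I", "II", paste0("V", 1:6))

#' Transmembrane-potential surrogate (sigmoidal upstroke)
#'
#' `vm(t) = 0.5 * (1 + tanh((t - AT) / tau))`: a smooth unit step centred at
#' the node's activation time.  Only the depolarisation upstroke matters for
#' the QRS, and the standardisation of the leads removes the absolute scale,
#' so a unit-amplitude template suffices.
#'
#' @param t time in ms (vectorised).
#' @param activation_time activation time(s) in ms.
#' @param upstroke_tau upstroke time constant in ms (> 0).
#' @return values in (0, 1).
#' @export
vm_waveform <- function(t, activation_time, upstroke_tau = 1) {
  if (upstroke_tau <= 0) stop("`upstroke_tau` must be positive")
  0.5 * (1 + tanh((t - activation_time) / upstroke_tau))
}

#' Precompute the pseudo-ECG lead-field matrix
#'
#' For electrode k and mesh node i, `W[k, i]` collects
#' `sum_e Vol_e * grad(phi_i)_e . grad(1/r_k)_e` over the elements `e`
#' containing node i, where `grad(phi_i)` is the linear (P1) shape-function
#' gradient and `r_k` the element-centroid-to-electrode distance.  The
#' electrode potential is then `phi_k(t) = -K * W[k, ] %*% vm(t)`, linear in
#' the membrane potential.
#'
#' @param mesh a `bivmesh`.
#' @param electrodes an `electrode_set`.
#' @return object of class `lead_field` (matrix `n_electrodes x n_nodes`
#'   with electrode names as rownames).
#' @export
lead_field <- function(mesh, electrodes) {
  stopifnot(inherits(mesh, "bivmesh"), inherits(electrodes, "electrode_set"))
  el <- mesh$elements
  nn <- nrow(mesh$nodes)
  ne <- nrow(el)
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  p4 <- mesh$nodes[el[, 4], , drop = FALSE]
  cent <- (p1 + p2 + p3 + p4) / 4
  vol <- mesh$element_volume

  # P1 gradients: grad(lambda_j) rows; lambda_1 gradient = -(g2+g3+g4)
  # For tet (p1..p4): g_j = cross-product form / (6V)
  g2 <- .row_cross(p3 - p1, p4 - p1) / (6 * vol)
  g3 <- .row_cross(p4 - p1, p2 - p1) / (6 * vol)
  g4 <- .row_cross(p2 - p1, p3 - p1) / (6 * vol)
  g1 <- -(g2 + g3 + g4)

  epos <- as.matrix(electrodes[, c("x", "y", "z")])
  W <- matrix(0, nrow = nrow(epos), ncol = nn,
              dimnames = list(electrodes$name, NULL))
  for (k in seq_len(nrow(epos))) {
    d <- matrix(epos[k, ], ne, 3, byrow = TRUE) - cent
    r2 <- rowSums(d^2)
    r <- sqrt(r2)
    if (any(r < 1e-9)) stop("electrode ", electrodes$name[k],
                            " lies inside an element")
    L <- d / (r^3)                       # grad_source(1/r)
    contrib <- cbind(rowSums(g1 * L), rowSums(g2 * L),
                     rowSums(g3 * L), rowSums(g4 * L)) * vol
    Wk <- numeric(nn)
    for (j in 1:4) {
      acc <- tapply(contrib[, j], el[, j], sum)
      ids <- as.integer(names(acc))
      Wk[ids] <- Wk[ids] + as.numeric(acc)
    }
    W[k, ] <- Wk
  }
  structure(W, class = c("lead_field", "matrix"))
}

#' Electrode potential at one time instant
#'
#' @param atm an `activation_map` over the full mesh.
#' @param mesh the mesh.
#' @param electrode_position length-3 numeric (cm) or an `electrode_set`
#'   row.
#' @param t time in ms.
#' @param upstroke_tau upstroke time constant in ms.
#' @param K positive scaling constant (absolute scale is irrelevant after
#'   lead standardisation).
#' @return potential in arbitrary units.
#' @export
electrode_potential <- function(atm, mesh, electrode_position, t,
                                upstroke_tau = 1, K = 1) {
  pos <- as.numeric(electrode_position)
  es <- structure(data.frame(name = "E1", x = pos[1], y = pos[2], z = pos[3],
                             stringsAsFactors = FALSE),
                  class = c("electrode_set", "data.frame"))
  W <- lead_field(mesh, es)
  vm <- vm_waveform(t, atm$time_ms, upstroke_tau)
  as.numeric(-K * W %*% vm)
}

#' Compute a standardised 12-lead QRS complex from an activation map
#'
#' Potentials are simulated at the nine measurement electrodes (RA, LA, LL,
#' V1--V6) at 1 ms resolution over `[0, max(AT) + 5 tau]`; the 12 standard
#' leads are derived (Einthoven limb leads, Goldberger augmented leads,
#' Wilson central terminal for the precordials); each lead is standardised
#' by the maximum absolute amplitude across all 12 leads (preserving
#' inter-lead amplitude ratios) and the recording is trimmed to the QRS
#' support (samples where any lead exceeds 1 % of the peak).
#'
#' @param atm an `activation_map` over the full mesh.
#' @param mesh the mesh.
#' @param electrodes an `electrode_set`.
#' @param sampling_ms sampling interval (default 1 ms = 1 kHz).
#' @param upstroke_tau membrane upstroke time constant in ms.
#' @param lf optional precomputed [lead_field()] (recommended inside loops).
#' @param K scaling constant for the raw potentials.
#' @return object of class `qrs_recording`: `time_ms`, `leads` (samples x
#'   12 matrix), `duration_ms`, plus the pre-standardisation limb potentials
#'   in `raw_leads` for identity checks.
#' @export
compute_qrs <- function(atm, mesh, electrodes, sampling_ms = 1,
                        upstroke_tau = 1, lf = NULL, K = 1) {
  stopifnot(inherits(atm, "activation_map"))
  if (is.null(lf)) lf <- lead_field(mesh, electrodes)
  stopifnot(all(MEASURE_ELECTRODES %in% rownames(lf)))
  t_grid <- seq(0, max(atm$time_ms) + 5 * upstroke_tau, by = sampling_ms)
  # vm matrix: nodes x time
  Vm <- 0.5 * (1 + tanh(outer(-atm$time_ms, t_grid, "+") / upstroke_tau))
  phi <- -K * (lf[MEASURE_ELECTRODES, , drop = FALSE] %*% Vm)

  RA <- phi["RA", ]; LA <- phi["LA", ]; LL <- phi["LL", ]
  wct <- (RA + LA + LL) / 3
  leads <- cbind(
    I = LA - RA,
    II = LL - RA,
    III = LL - LA,
    aVR = RA - (LA + LL) / 2,
    aVL = LA - (RA + LL) / 2,
    aVF = LL - (RA + LA) / 2)
  prec <- t(phi[paste0("V", 1:6), , drop = FALSE] -
              matrix(wct, 6, length(wct), byrow = TRUE))
  colnames(prec) <- paste0("V", 1:6)
  leads <- cbind(leads, prec)

  peak <- max(abs(leads))
  if (peak <= 0) stop("degenerate activation: all potentials are zero")
  std <- leads / peak
  support <- which(apply(abs(std), 1, max) > 0.01)
  i0 <- min(support); i1 <- max(support)
  std <- std[i0:i1, , drop = FALSE]
  structure(list(time_ms = t_grid[i0:i1],
                 leads = std,
                 duration_ms = t_grid[i1] - t_grid[i0],
                 raw_leads = leads,
                 sampling_ms = sampling_ms),
            class = "qrs_recording")
}

#' @export
print.qrs_recording <- function(x, ...) {
  cat(sprintf("12-lead QRS: %d samples @ %g ms, width %.0f ms\n",
              nrow(x$leads), x$sampling_ms %||% 1, x$duration_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
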