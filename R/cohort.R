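# Virtual subjects: ground-truth parameter-sets plus clean and 20 dB
# noise-contaminated target data (epicardial activation maps and 12-lead
# QRS), built so the inference can be evaluated against a known truth.

#' The five named conduction-speed configurations
#'
#' Speed presets spanning the variability of the healthy human population:
#' Normal (150/50/32/29), Slow endocardial (120/50/32/29), Fast endocardial
#' (179/50/32/29), Fast endocardial and myocardial (179/88/49/45), Slow
#' endocardial and fast myocardial (120/88/49/45) cm/s (endocardial / fibre
#' / sheet / sheet-normal).
#'
#' @return named list of `conduction_speeds`.
#' @export
speed_configurations <- function() {
  list(
    "Normal speeds" = conduction_speeds(150, 50, 32, 29),
    "Slow endocardial speed" = conduction_speeds(120, 50, 32, 29),
    "Fast endocardial speed" = conduction_speeds(179, 50, 32, 29),
    "Fast endocardial and myocardial speeds" =
      conduction_speeds(179, 88, 49, 45),
    "Slow endocardial and fast myocardial speeds" =
      conduction_speeds(120, 88, 49, 45))
}

#' Contaminate target data with white Gaussian noise at a given SNR
#'
#' Additive i.i.d. Gaussian noise with variance `signal_power /
#' 10^(snr_db/10)`, where the signal power is the mean square over the
#' signal support (all epicardial nodes for activation maps; all samples of
#' all leads for QRS recordings).  Deterministic given `seed`.
#'
#' @param signal an `activation_map`, `qrs_recording`, or numeric vector.
#' @param snr_db target signal-to-noise ratio in dB (default 20).
#' @param seed RNG seed.
#' @return the noisy signal, same class as the input.
#' @export
add_white_noise <- function(signal, snr_db = 20, seed = 1L) {
  UseMethod("add_white_noise")
}

.noise_sd <- function(x, snr_db) {
  p <- mean(x^2)
  if (p <= 0) stop("zero-power signal cannot be noise-contaminated")
  sqrt(p / 10^(snr_db / 10))
}

#' @export
add_white_noise.numeric <- function(signal, snr_db = 20, seed = 1L) {
  set.seed(seed)
  signal + rnorm(length(signal), 0, .noise_sd(signal, snr_db))
}

#' @export
add_white_noise.activation_map <- function(signal, snr_db = 20, seed = 1L) {
  set.seed(seed)
  out <- signal
  out$time_ms <- signal$time_ms +
    rnorm(length(signal$time_ms), 0, .noise_sd(signal$time_ms, snr_db))
  out
}

#' @export
add_white_noise.qrs_recording <- function(signal, snr_db = 20, seed = 1L) {
  set.seed(seed)
  out <- signal
  sdn <- .noise_sd(as.numeric(signal$leads), snr_db)
  noise <- matrix(rnorm(length(signal$leads), 0, sdn),
                  nrow = nrow(signal$leads))
  out$leads <- signal$leads + noise
  out
}

#' Empirical SNR of a contaminated signal against its clean original
#'
#' `10 * log10(signal power / noise power)` with powers measured over the
#' signal support.
#'
#' @param clean,noisy matching signals.
#' @return SNR estimate in dB.
#' @export
empirical_snr_db <- function(clean, noisy) {
  get_vals <- function(x) {
    if (inherits(x, "activation_map")) x$time_ms
    else if (inherits(x, "qrs_recording")) as.numeric(x$leads)
    else as.numeric(x)
  }
  s <- get_vals(clean)
  n <- get_vals(noisy) - s
  10 * log10(mean(s^2) / mean(n^2))
}

#' Build one virtual subject
#'
#' Samples `n_roots` ground-truth root nodes uniformly from the candidate
#' set (seeded), simulates the clean epicardial activation map and 12-lead
#' QRS through the forward modules, and attaches 20 dB noise-contaminated
#' variants of both.
#'
#' @param mesh a `bivmesh`.
#' @param candidates a `root_candidates` (the truth is drawn from this set;
#'   by default the low-resolution set, so higher-resolution inference must
#'   interpolate).
#' @param speeds a `conduction_speeds` (e.g. from [speed_configurations()]).
#' @param n_roots number of true root nodes in `[6, 10]`.
#' @param seed RNG seed (controls root sampling and both noise draws).
#' @param electrodes optional `electrode_set` (placed automatically if
#'   missing).
#' @param snr_db noise level of the contaminated targets.
#' @param upstroke_tau pseudo-ECG upstroke constant (ms).
#' @return object of class `virtual_subject`.
#' @export
make_virtual_subject <- function(mesh, candidates, speeds, n_roots = 7,
                                 seed = 1L, electrodes = NULL,
                                 snr_db = 20, upstroke_tau = 1) {
  if (n_roots < ROOT_COUNT_RANGE[1] || n_roots > ROOT_COUNT_RANGE[2])
    stop("`n_roots` must lie in [6, 10]")
  if (is.null(electrodes)) electrodes <- place_electrodes(mesh)
  set.seed(seed)
  act <- rep(FALSE, length(candidates$node_id))
  act[sample.int(length(act), n_roots)] <- TRUE
  truth <- parameter_set(speeds, act)
  atm_full <- simulate_activation(mesh, candidates, truth)
  atm_clean <- extract_epicardial_map(atm_full, mesh)
  qrs_clean <- compute_qrs(atm_full, mesh, electrodes,
                           upstroke_tau = upstroke_tau)
  structure(list(
    mesh = mesh, candidates = candidates, electrodes = electrodes,
    truth = truth,
    truth_root_node_ids = candidates$node_id[act],
    atm_clean = atm_clean,
    atm_noisy = add_white_noise(atm_clean, snr_db, seed = seed + 1000L),
    qrs_clean = qrs_clean,
    qrs_noisy = add_white_noise(qrs_clean, snr_db, seed = seed + 2000L),
    seed = as.integer(seed), snr_db = snr_db,
    upstroke_tau = upstroke_tau
  ), class = "virtual_subject")
}

#' Build the full virtual cohort (anatomies x speed presets)
#'
#' The default cohort crosses the four anatomy presets with the five
#' conduction-speed configurations, giving twenty virtual subjects.  The
#' manifest of seeds makes the cohort bit-reproducible.
#'
#' @param anatomies character vector of [anatomy_preset()] names.
#' @param presets names from [speed_configurations()] (default: all five).
#' @param edge_length mesh resolution in cm.
#' @param n_roots true root-node count per subject.
#' @param seed base seed; subject seeds are derived deterministically.
#' @param resolution candidate discretisation the truth is drawn from.
#' @return list with `subjects` (list of `virtual_subject`) and `manifest`
#'   (data.frame of anatomy, preset, seed).
#' @export
make_cohort <- function(anatomies = c("small", "medium", "large", "xlarge"),
                        presets = names(speed_configurations()),
                        edge_length = 0.5, n_roots = 7, seed = 1L,
                        resolution = "LOW") {
  cfgs <- speed_configurations()
  stopifnot(all(presets %in% names(cfgs)))
  manifest <- expand.grid(anatomy = anatomies, preset = presets,
                          stringsAsFactors = FALSE)
  manifest$seed <- seed + seq_len(nrow(manifest))
  subjects <- vector("list", nrow(manifest))
  meshes <- list()
  for (an in anatomies) {
    ap <- anatomy_preset(an)
    m <- generate_synthetic_mesh(axes = ap$axes,
                                 wall_thickness = ap$wall_thickness,
                                 edge_length = edge_length,
                                 rv_bulge = ap$rv_bulge,
                                 rv_halfwidth_deg = ap$rv_halfwidth_deg,
                                 rv_apex_deg = ap$rv_apex_deg)
    meshes[[an]] <- list(mesh = m,
                         candidates = discretise_root_candidates(m, resolution),
                         electrodes = place_electrodes(m))
  }
  for (i in seq_len(nrow(manifest))) {
    mm <- meshes[[manifest$anatomy[i]]]
    subjects[[i]] <- make_virtual_subject(
      mm$mesh, mm$candidates, cfgs[[manifest$preset[i]]],
      n_roots = n_roots, seed = manifest$seed[i],
      electrodes = mm$electrodes)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Write a virtual subject bundle to disk
#'
#' Writes the mesh (VTK + CSV triplet), electrodes, candidates, the four
#' targets (`atm_clean.csv`, `atm_noisy.csv`, `qrs_clean.csv`,
#' `qrs_noisy.csv`), `truth.json` and `manifest.json` into `dir`.
#'
#' @param subject a `virtual_subject`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_subject_bundle <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh_vtk(subject$mesh, file.path(dir, "mesh.vtk"))
  write_mesh_csv(subject$mesh, dir)
  write_electrodes_csv(subject$electrodes, file.path(dir, "electrodes.csv"))
  write_candidates_csv(subject$candidates, file.path(dir, "candidates.csv"))
  write_atm_csv(subject$atm_clean, file.path(dir, "atm_clean.csv"))
  write_atm_csv(subject$atm_noisy, file.path(dir, "atm_noisy.csv"))
  write_qrs_csv(subject$qrs_clean, file.path(dir, "qrs_clean.csv"))
  write_qrs_csv(subject$qrs_noisy, file.path(dir, "qrs_noisy.csv"))
  jsonlite::write_json(list(
    speeds = as.list(unclass(subject$truth$speeds)),
    root_node_ids = subject$truth_root_node_ids - 1L,
    n_roots = sum(subject$truth$root_active)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    seed = subject$seed, snr_db = subject$snr_db,
    upstroke_tau = subject$upstroke_tau,
    candidate_resolution = subject$candidates$resolution,
    anatomy = subject$mesh$anatomy),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("Virtual subject\n")
  cat(sprintf("  speeds (cm/s): %s\n",
              paste(sprintf("%s=%g", names(x$truth$speeds),
                            unclass(x$truth$speeds)), collapse = ", ")))
  cat(sprintf("  true root nodes: %d   QRS width: %.0f ms\n",
              sum(x$truth$root_active), x$qrs_clean$duration_ms))
  invisible(x)
}
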