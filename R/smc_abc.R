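# Sequential Monte Carlo approximate Bayesian computation over the mixed
# parameter space (four continuous conduction speeds + a discrete subset of
# candidate root nodes).  The population of parameter-sets is evolved by
# repeatedly replacing the worst 12.5 % (highest discrepancy) with mutated
# or plain copies of surviving members, until every member matches the
# target within tolerance or the population collapses into duplicates.

SPEED_BOUNDS <- list(endocardial = c(100, 200), myocardial = c(25, 90))
ROOT_COUNT_RANGE <- c(6L, 10L)

#' Inference configuration
#'
#' @param population_size number of parameter-sets evolved (default 512).
#' @param replacement_fraction fraction replaced per iteration (default
#'   0.125, i.e. the top 12.5 % highest discrepancies).
#' @param tolerance match threshold on the discrepancy; `NULL` defers to
#'   [default_tolerance()] computed from the target's 20 dB noise scale.
#' @param duplicate_fraction_threshold stop when the fraction of duplicated
#'   parameter-sets exceeds this (strictly; default 0.5).
#' @param max_iterations safety bound on the number of iterations.
#' @param kernel mutation kernel: `sigma_endo` / `sigma_myo` (cm/s,
#'   truncated-Gaussian widths), `root_change_prob` (probability that the
#'   root-node subset is modified at all), `move_radius_cm` (radius for the
#'   relocate move).
#' @param seed RNG seed governing the whole run.
#' @return object of class `inference_config`.
#' @export
inference_config <- function(population_size = 512L,
                             replacement_fraction = 0.125,
                             tolerance = NULL,
                             duplicate_fraction_threshold = 0.5,
                             max_iterations = 100L,
                             kernel = list(sigma_endo = 5, sigma_myo = 2.5,
                                           root_change_prob = 0.5,
                                           move_radius_cm = 2),
                             seed = 1L) {
  if (replacement_fraction <= 0 || replacement_fraction >= 1)
    stop("`replacement_fraction` must lie in (0, 1)")
  if (duplicate_fraction_threshold <= 0 || duplicate_fraction_threshold > 1)
    stop("`duplicate_fraction_threshold` must lie in (0, 1]")
  if (population_size < 2) stop("`population_size` must be at least 2")
  structure(list(population_size = as.integer(population_size),
                 replacement_fraction = replacement_fraction,
                 tolerance = tolerance,
                 duplicate_fraction_threshold = duplicate_fraction_threshold,
                 max_iterations = as.integer(max_iterations),
                 kernel = kernel,
                 seed = as.integer(seed)),
            class = "inference_config")
}

# canonical key used for duplicate detection (bitwise equality of the full
# parameter vector)
.member_key <- function(member) {
  paste(c(sprintf("%.17g", unclass(member$speeds)),
          paste(as.integer(member$root_active), collapse = "")),
        collapse = "|")
}

.duplicate_count <- function(pop) {
  keys <- vapply(pop$members, .member_key, character(1))
  length(keys) - length(unique(keys))
}

#' Sample the prior population by Latin hypercube sampling
#'
#' Speeds are drawn by Latin-hypercube stratification over the box
#' `[100,200] x [25,90]^3`, with the three myocardial coordinates reordered
#' descending to enforce fibre >= sheet >= sheet-normal.  The number of
#' active root nodes is uniform on 6..10 and that many candidates are drawn
#' uniformly without replacement.
#'
#' @param candidates a `root_candidates` object.
#' @param n population size (>= 2).
#' @param seed RNG seed.
#' @return object of class `population` (discrepancies not yet evaluated).
#' @export
sample_prior_lhs <- function(candidates, n, seed = 1L) {
  if (n < 2) stop("`n` must be at least 2")
  nc <- length(candidates$node_id)
  if (nc < ROOT_COUNT_RANGE[2])
    stop("candidate set too small for the root-node count range")
  capacity <- sum(choose(nc, ROOT_COUNT_RANGE[1]:ROOT_COUNT_RANGE[2]))
  if (n > capacity)
    stop("population size exceeds the number of distinct root configurations")
  set.seed(seed)
  lhs <- function(lo, hi) {
    u <- (sample.int(n) - runif(n)) / n
    lo + u * (hi - lo)
  }
  endo <- lhs(100, 200)
  myo <- cbind(lhs(25, 90), lhs(25, 90), lhs(25, 90))
  myo <- t(apply(myo, 1, sort, decreasing = TRUE))
  counts <- sample(ROOT_COUNT_RANGE[1]:ROOT_COUNT_RANGE[2], n, replace = TRUE)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    act <- rep(FALSE, nc)
    act[sample.int(nc, counts[i])] <- TRUE
    members[[i]] <- parameter_set(
      conduction_speeds(endo[i], myo[i, 1], myo[i, 2], myo[i, 3]), act)
  }
  structure(list(members = members,
                 discrepancy = rep(NA_real_, n),
                 iteration = 0L, seed = as.integer(seed)),
            class = "population")
}

#' Build the forward simulator closure for one mesh / candidate set
#'
#' Precomputes the propagation graph (and the pseudo-ECG lead field for the
#' ECG modality) once, and returns a function mapping a `parameter_set` to
#' the predicted target-modality data (epicardial activation map or 12-lead
#' QRS).
#'
#' @param mesh a `bivmesh`.
#' @param candidates a `root_candidates`.
#' @param modality `"ATM"` or `"ECG"`.
#' @param electrodes an `electrode_set` (required for `"ECG"`).
#' @param upstroke_tau pseudo-ECG membrane upstroke constant (ms).
#' @return a closure `function(params)`.
#' @export
make_forward <- function(mesh, candidates, modality = c("ATM", "ECG"),
                         electrodes = NULL, upstroke_tau = 1) {
  modality <- match.arg(modality)
  graph <- eikonal_graph(mesh)
  if (modality == "ECG") {
    if (is.null(electrodes)) stop("ECG modality requires electrodes")
    lf <- lead_field(mesh, electrodes)
    function(params) {
      atm <- simulate_activation(mesh, candidates, params, graph)
      compute_qrs(atm, mesh, electrodes, upstroke_tau = upstroke_tau, lf = lf)
    }
  } else {
    function(params) {
      atm <- simulate_activation(mesh, candidates, params, graph)
      extract_epicardial_map(atm, mesh)
    }
  }
}

# single-member discrepancy, with sentinel on simulator failure
.member_discrepancy <- function(member, forward, target, modality, dtw_cfg) {
  pred <- tryCatch(forward(member), error = function(e) e)
  if (inherits(pred, "error")) {
    warning("simulator failure: ", conditionMessage(pred), call. = FALSE)
    return(.Machine$double.xmax)
  }
  if (modality == "ATM") as.numeric(atm_rmse(pred, target))
  else as.numeric(ecg_discrepancy(pred, target, dtw_cfg))
}

#' Evaluate the discrepancy of every member of a population
#'
#' @param pop a `population`.
#' @param forward forward-simulator closure from [make_forward()].
#' @param target target data matching `modality`.
#' @param modality `"ATM"` or `"ECG"`.
#' @param dtw_cfg a [dtw_config()] for the ECG modality.
#' @return the population with `discrepancy` filled in (order-independent).
#' @export
evaluate_population <- function(pop, forward, target,
                                modality = c("ATM", "ECG"),
                                dtw_cfg = dtw_config()) {
  modality <- match.arg(modality)
  if (modality == "ATM" && !inherits(target, "activation_map"))
    stop("ATM modality requires an activation_map target")
  if (modality == "ECG" && !inherits(target, "qrs_recording"))
    stop("ECG modality requires a qrs_recording target")
  pop$discrepancy <- vapply(pop$members, .member_discrepancy, numeric(1),
                            forward, target, modality, dtw_cfg)
  pop
}

#' Select the members to be replaced
#'
#' The `ceiling(fraction * size)` members with the highest discrepancies
#' (ties broken by member index: earlier members survive) are marked for
#' replacement; the cut-off is the highest discrepancy among the survivors.
#'
#' @param pop evaluated `population`.
#' @param replacement_fraction fraction in (0, 1).
#' @return list with `cutoff`, `replace_idx`, `survivor_idx`.
#' @export
select_replacement_set <- function(pop, replacement_fraction = 0.125) {
  if (anyNA(pop$discrepancy)) stop("population not evaluated")
  n <- length(pop$members)
  k <- as.integer(ceiling(replacement_fraction * n))
  ord <- order(pop$discrepancy, seq_len(n), decreasing = TRUE)
  # `order` with two keys and decreasing=TRUE reverses the index tie-break;
  # re-sort ties explicitly: highest discrepancy first, then highest index
  ord <- ord[order(-pop$discrepancy[ord], -ord)]
  replace_idx <- sort(ord[seq_len(k)])
  survivor_idx <- setdiff(seq_len(n), replace_idx)
  list(cutoff = max(pop$discrepancy[survivor_idx]),
       replace_idx = replace_idx,
       survivor_idx = survivor_idx)
}

# truncated-Gaussian perturbation by rejection, clamped after 100 tries
.trunc_norm <- function(x, sigma, lo, hi) {
  if (sigma == 0) return(x)
  for (i in 1:100) {
    y <- rnorm(1, x, sigma)
    if (y >= lo && y <= hi) return(y)
  }
  min(max(x, lo), hi)
}

#' MCMC mutation of one parameter-set
#'
#' Speeds are perturbed by truncated Gaussians within their bounds, with the
#' myocardial ordering restored by a descending sort.  With probability
#' `kernel$root_change_prob` the root-node subset is modified by one of two
#' moves (chosen uniformly): toggle one candidate, or relocate one active
#' root to a uniformly chosen inactive candidate within
#' `kernel$move_radius_cm` (falling back to any inactive candidate when none
#' is in range).  Proposals violating the root-count range are re-drawn up
#' to 10 times, after which the original subset is kept.
#'
#' @param member a `parameter_set`.
#' @param kernel kernel list as in [inference_config()].
#' @param candidates the `root_candidates` the member is defined over.
#' @param coords optional candidate coordinate matrix (rows match
#'   candidates); required for the relocate move radius.
#' @return a valid `parameter_set`.
#' @export
mutate <- function(member, kernel, candidates, coords = NULL) {
  v <- member$speeds
  endo <- .trunc_norm(v[["endocardial"]], kernel$sigma_endo, 100, 200)
  myo <- vapply(c("fibre", "sheet", "sheet_normal"),
                function(nm) .trunc_norm(v[[nm]], kernel$sigma_myo, 25, 90),
                numeric(1))
  myo <- sort(myo, decreasing = TRUE)
  speeds <- conduction_speeds(endo, myo[1], myo[2], myo[3])

  act <- member$root_active
  if (kernel$root_change_prob > 0 && runif(1) < kernel$root_change_prob) {
    nc <- length(act)
    ok <- FALSE
    for (try in 1:10) {
      prop <- act
      if (runif(1) < 0.5) {                        # toggle
        i <- sample.int(nc, 1)
        prop[i] <- !prop[i]
      } else {                                     # relocate
        on <- which(prop); off <- which(!prop)
        if (length(off) > 0) {
          src <- on[sample.int(length(on), 1)]
          pool <- off
          if (!is.null(coords)) {
            d <- sqrt(rowSums((coords[off, , drop = FALSE] -
                matrix(coords[src, ], length(off), 3, byrow = TRUE))^2))
            near <- off[d <= kernel$move_radius_cm]
            if (length(near) > 0) pool <- near
          }
          dst <- pool[sample.int(length(pool), 1)]
          prop[src] <- FALSE
          prop[dst] <- TRUE
        }
      }
      k <- sum(prop)
      if (k >= ROOT_COUNT_RANGE[1] && k <= ROOT_COUNT_RANGE[2]) {
        act <- prop; ok <- TRUE; break
      }
    }
    if (!ok) act <- member$root_active              # identity fallback
  }
  parameter_set(speeds, act)
}

#' One SMC-ABC replacement step
#'
#' Each member marked for replacement is replaced by a mutated copy of a
#' uniformly chosen survivor if the mutant's discrepancy beats the cut-off,
#' and by the unmodified survivor copy otherwise.  Survivors are never
#' modified and the population size is unchanged.
#'
#' @param pop evaluated `population`.
#' @param forward,target,modality,dtw_cfg as in [evaluate_population()].
#' @param cfg an `inference_config`.
#' @param candidates,coords as in [mutate()].
#' @return the updated `population`.
#' @export
replacement_step <- function(pop, forward, target, modality, cfg,
                             candidates, coords = NULL,
                             dtw_cfg = dtw_config()) {
  sel <- select_replacement_set(pop, cfg$replacement_fraction)
  for (idx in sel$replace_idx) {
    src <- sel$survivor_idx[sample.int(length(sel$survivor_idx), 1)]
    mutant <- mutate(pop$members[[src]], cfg$kernel, candidates, coords)
    d_m <- .member_discrepancy(mutant, forward, target, modality, dtw_cfg)
    if (d_m < sel$cutoff) {
      pop$members[[idx]] <- mutant
      pop$discrepancy[idx] <- d_m
    } else {
      pop$members[[idx]] <- pop$members[[src]]
      pop$discrepancy[idx] <- pop$discrepancy[src]
    }
  }
  pop$iteration <- pop$iteration + 1L
  pop
}

#' Evaluate the stopping criteria
#'
#' `MATCHED` when every discrepancy is at most the tolerance; `COLLAPSED`
#' when the duplicate fraction strictly exceeds the threshold (a duplicate
#' is an exact copy of the full parameter vector); `MATCHED` takes
#' precedence.
#'
#' @param pop evaluated `population`.
#' @param cfg an `inference_config` (with resolved numeric `tolerance`).
#' @return one of `"MATCHED"`, `"COLLAPSED"`, `"CONTINUE"`.
#' @export
check_stopping <- function(pop, cfg) {
  if (anyNA(pop$discrepancy)) stop("population not evaluated")
  if (is.null(cfg$tolerance)) stop("tolerance not resolved")
  if (all(pop$discrepancy <= cfg$tolerance)) return("MATCHED")
  dup_frac <- .duplicate_count(pop) / length(pop$members)
  if (dup_frac > cfg$duplicate_fraction_threshold) return("COLLAPSED")
  "CONTINUE"
}

#' Default ABC tolerance from the 20 dB noise scale of the target
#'
#' The tolerance is the mean discrepancy between the clean target and
#' independent 20 dB-SNR noise realisations of it, i.e. the distortion level
#' that the noise-contamination protocol itself introduces.
#'
#' @param target clean target (`activation_map` or `qrs_recording`).
#' @param modality `"ATM"` or `"ECG"`.
#' @param n_realisations number of noise realisations averaged.
#' @param snr_db signal-to-noise ratio of the protocol.
#' @param seed RNG seed.
#' @param dtw_cfg DTW configuration for the ECG modality.
#' @return scalar tolerance.
#' @export
default_tolerance <- function(target, modality = c("ATM", "ECG"),
                              n_realisations = 10, snr_db = 20, seed = 1L,
                              dtw_cfg = dtw_config()) {
  modality <- match.arg(modality)
  vals <- vapply(seq_len(n_realisations), function(i) {
    noisy <- add_white_noise(target, snr_db, seed = seed + i)
    if (modality == "ATM") as.numeric(atm_rmse(noisy, target))
    else as.numeric(ecg_discrepancy(noisy, target, dtw_cfg))
  }, numeric(1))
  mean(vals)
}

#' Run the full SMC-ABC inference
#'
#' Iterates evaluate / check-stopping / replace until a stopping criterion
#' fires or `max_iterations` is reached.  Fully reproducible given
#' `cfg$seed`.
#'
#' @param mesh a `bivmesh`.
#' @param candidates a `root_candidates`.
#' @param target target data (`activation_map` restricted to the epicardium,
#'   or `qrs_recording`).
#' @param modality `"ATM"` or `"ECG"`.
#' @param cfg an `inference_config`.
#' @param electrodes an `electrode_set` (ECG modality).
#' @param dtw_cfg a [dtw_config()] (ECG modality).
#' @param upstroke_tau pseudo-ECG upstroke constant (ms).
#' @param verbose print one line per iteration to stderr.
#' @return list with `population`, `trace` (per-iteration data.frame),
#'   `status`, `tolerance`.
#' @export
run_inference <- function(mesh, candidates, target,
                          modality = c("ATM", "ECG"),
                          cfg = inference_config(),
                          electrodes = NULL, dtw_cfg = dtw_config(),
                          upstroke_tau = 1, verbose = FALSE) {
  modality <- match.arg(modality)
  set.seed(cfg$seed)
  if (is.null(cfg$tolerance))
    cfg$tolerance <- default_tolerance(target, modality, seed = cfg$seed,
                                       dtw_cfg = dtw_cfg)
  forward <- make_forward(mesh, candidates, modality, electrodes,
                          upstroke_tau)
  coords <- mesh$nodes[candidates$node_id, , drop = FALSE]
  pop <- sample_prior_lhs(candidates, cfg$population_size, cfg$seed)
  pop <- evaluate_population(pop, forward, target, modality, dtw_cfg)

  trace <- list()
  status <- "MAX_ITERATIONS"
  for (it in seq_len(cfg$max_iterations)) {
    sel <- select_replacement_set(pop, cfg$replacement_fraction)
    dup_frac <- .duplicate_count(pop) / length(pop$members)
    trace[[it]] <- data.frame(
      iteration = pop$iteration, cutoff = sel$cutoff,
      min = min(pop$discrepancy), median = median(pop$discrepancy),
      max = max(pop$discrepancy), duplicate_fraction = dup_frac)
    if (verbose)
      message(sprintf(
        "iter %3d  cutoff %.4g  min %.4g  median %.4g  max %.4g  dup %.0f%%",
        pop$iteration, sel$cutoff, min(pop$discrepancy),
        median(pop$discrepancy), max(pop$discrepancy), 100 * dup_frac))
    st <- check_stopping(pop, cfg)
    if (st != "CONTINUE") { status <- st; break }
    pop <- replacement_step(pop, forward, target, modality, cfg,
                            candidates, coords, dtw_cfg)
  }
  list(population = pop, trace = do.call(rbind, trace), status = status,
       tolerance = cfg$tolerance)
}

#' Write / read a population as CSV
#'
#' One row per member: the four speeds, the candidate bitmask (string of
#' 0/1), and the discrepancy.
#'
#' @param pop a `population`.
#' @param path file path.
#' @return the path / the loaded `population`.
#' @export
write_population_csv <- function(pop, path) {
  df <- data.frame(
    endocardial = vapply(pop$members, function(m) m$speeds[["endocardial"]], 1),
    fibre = vapply(pop$members, function(m) m$speeds[["fibre"]], 1),
    sheet = vapply(pop$members, function(m) m$speeds[["sheet"]], 1),
    sheet_normal = vapply(pop$members, function(m) m$speeds[["sheet_normal"]], 1),
    root_bitmask = vapply(pop$members, function(m)
      paste(as.integer(m$root_active), collapse = ""), ""),
    discrepancy = pop$discrepancy)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- read.csv(path, colClasses = c(root_bitmask = "character"))
  members <- lapply(seq_len(nrow(df)), function(i) {
    act <- as.integer(strsplit(df$root_bitmask[i], "")[[1]]) == 1L
    parameter_set(conduction_speeds(df$endocardial[i], df$fibre[i],
                                    df$sheet[i], df$sheet_normal[i]), act)
  })
  structure(list(members = members, discrepancy = df$discrepancy,
                 iteration = NA_integer_, seed = NA_integer_),
            class = "population")
}
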