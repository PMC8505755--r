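# the engine is tested on small populations with scripted forward closures
# (allowed: the closure contract is just parameter_set -> prediction)

scripted_forward <- function(node_ids = 1:5) {
  # prediction depends only on the fibre speed -> 1-D identifiable problem
  function(params) {
    structure(list(node_id = node_ids,
                   time_ms = rep(params$speeds[["fibre"]], length(node_ids))),
              class = "activation_map")
  }
}

scripted_target <- function(value = 50, node_ids = 1:5) {
  structure(list(node_id = node_ids, time_ms = rep(value, length(node_ids))),
            class = "activation_map")
}

test_that("prior sampling respects bounds, ordering, counts and LHS strata", {
  cand <- fixture_candidates("HIGH")
  n <- 64
  pop <- sample_prior_lhs(cand, n, seed = 3)
  expect_length(pop$members, n)
  sp <- t(vapply(pop$members, function(m) unclass(m$speeds), numeric(4)))
  expect_true(all(sp[, 1] >= 100 & sp[, 1] <= 200))
  expect_true(all(sp[, 2:4] >= 25 & sp[, 2:4] <= 90))
  expect_true(all(sp[, 2] >= sp[, 3] & sp[, 3] >= sp[, 4]))
  counts <- vapply(pop$members, function(m) sum(m$root_active), integer(1))
  expect_true(all(counts >= 6 & counts <= 10))
  # Latin hypercube property on the endocardial dimension: one sample per
  # stratum
  strata <- findInterval(sp[, 1], seq(100, 200, length.out = n + 1),
                         rightmost.closed = TRUE)
  expect_setequal(strata, 1:n)
  # determinism
  pop2 <- sample_prior_lhs(cand, n, seed = 3)
  expect_identical(lapply(pop$members, unclass),
                   lapply(pop2$members, unclass))
  expect_error(sample_prior_lhs(cand, 1), "at least 2")
})

test_that("population evaluation is order-independent and per-member exact", {
  cand <- fixture_candidates("LOW")
  fwd <- scripted_forward()
  target <- scripted_target(50)
  pop <- sample_prior_lhs(cand, 4, seed = 11)
  pop <- evaluate_population(pop, fwd, target, "ATM")
  manual <- vapply(pop$members, function(m)
    abs(m$speeds[["fibre"]] - 50), numeric(1))
  expect_equal(pop$discrepancy, manual, tolerance = 1e-12)
  # permuting the population permutes the discrepancies identically
  perm <- c(3, 1, 4, 2)
  pop_p <- pop
  pop_p$members <- pop$members[perm]
  pop_p <- evaluate_population(pop_p, fwd, target, "ATM")
  expect_equal(pop_p$discrepancy, pop$discrepancy[perm])
  expect_error(evaluate_population(pop, fwd, list(), "ATM"), "activation_map")
})

test_that("replacement selection takes the worst members with index ties", {
  cand <- fixture_candidates("LOW")
  pop <- sample_prior_lhs(cand, 8, seed = 2)
  pop$discrepancy <- as.numeric(1:8)
  sel <- select_replacement_set(pop, 0.125)
  expect_identical(sel$replace_idx, 8L)
  expect_equal(sel$cutoff, 7)
  # all-equal discrepancies: still exactly ceil(f*n), highest indices first
  pop$discrepancy <- rep(2, 8)
  sel <- select_replacement_set(pop, 0.25)
  expect_identical(sel$replace_idx, c(7L, 8L))
  expect_equal(sel$cutoff, 2)
  # 0.125 * 16 = 2
  pop16 <- sample_prior_lhs(cand, 16, seed = 2)
  pop16$discrepancy <- runif(16)
  sel <- select_replacement_set(pop16, 0.125)
  expect_length(sel$replace_idx, 2)
  expect_setequal(sel$replace_idx, order(pop16$discrepancy,
                                         decreasing = TRUE)[1:2])
})

test_that("mutation preserves all parameter-set invariants", {
  cand <- fixture_candidates("LOW")
  coords <- fixture_mesh()$nodes[cand$node_id, , drop = FALSE]
  member <- fixture_params()
  # degenerate kernel: exact identity
  set.seed(1)
  m0 <- mutate(member, list(sigma_endo = 0, sigma_myo = 0,
                            root_change_prob = 0, move_radius_cm = 2),
               cand, coords)
  expect_identical(unclass(m0$speeds), unclass(member$speeds))
  expect_identical(m0$root_active, member$root_active)
  # closure under invariants over many draws
  kernel <- list(sigma_endo = 5, sigma_myo = 2.5, root_change_prob = 0.5,
                 move_radius_cm = 2)
  set.seed(2)
  for (i in 1:1000) {
    m <- mutate(member, kernel, cand, coords)
    sp <- unclass(m$speeds)
    expect_true(sp[1] >= 100 && sp[1] <= 200)
    expect_true(all(sp[2:4] >= 25 & sp[2:4] <= 90))
    expect_true(sp[2] >= sp[3] && sp[3] >= sp[4])
    k <- sum(m$root_active)
    expect_true(k >= 6 && k <= 10)
    member <- m
  }
})

test_that("empirical mutation kernel width matches the configured sigma", {
  cand <- fixture_candidates("LOW")
  member <- fixture_params()                  # endo = 150: far from bounds
  kernel <- list(sigma_endo = 5, sigma_myo = 0, root_change_prob = 0,
                 move_radius_cm = 2)
  set.seed(4)
  draws <- replicate(1e4,
    mutate(member, kernel, cand)$speeds[["endocardial"]])
  expect_lt(abs(sd(draws - 150) - 5) / 5, 0.05)
})

test_that("replacement step obeys the cut-off contract", {
  cand <- fixture_candidates("LOW")
  fwd <- scripted_forward()
  target <- scripted_target(50)
  cfg <- inference_config(population_size = 8, seed = 5,
                          kernel = list(sigma_endo = 3, sigma_myo = 1.5,
                                        root_change_prob = 0.5,
                                        move_radius_cm = 2))
  pop <- sample_prior_lhs(cand, 8, seed = 5)
  pop <- evaluate_population(pop, fwd, target, "ATM")
  sel <- select_replacement_set(pop, cfg$replacement_fraction)
  set.seed(99)
  new_pop <- replacement_step(pop, fwd, target, "ATM", cfg, cand)
  expect_length(new_pop$members, 8)
  expect_lte(max(new_pop$discrepancy), sel$cutoff)
  # survivors untouched
  for (i in sel$survivor_idx)
    expect_identical(unclass(new_pop$members[[i]]),
                     unclass(pop$members[[i]]))
  # degenerate kernel: replaced slots are exact survivor duplicates
  cfg0 <- cfg
  cfg0$kernel <- list(sigma_endo = 0, sigma_myo = 0, root_change_prob = 0,
                      move_radius_cm = 2)
  set.seed(7)
  dup_pop <- replacement_step(pop, fwd, target, "ATM", cfg0, cand)
  keys <- vapply(dup_pop$members, cardioinfer:::.member_key, character(1))
  for (i in sel$replace_idx)
    expect_true(keys[i] %in% keys[sel$survivor_idx])
})

test_that("stopping criteria follow the strict boundary definitions", {
  cand <- fixture_candidates("LOW")
  cfg <- inference_config(population_size = 8, tolerance = 1)
  pop <- sample_prior_lhs(cand, 8, seed = 6)
  # 5/8 duplicates (> 0.5): collapse
  for (i in 2:6) pop$members[[i]] <- pop$members[[1]]
  pop$discrepancy <- rep(2, 8)
  expect_identical(check_stopping(pop, cfg), "COLLAPSED")
  # exactly 4/8 duplicates (= 0.5, strict "more than"): continue
  pop2 <- sample_prior_lhs(cand, 8, seed = 6)
  for (i in 2:5) pop2$members[[i]] <- pop2$members[[1]]
  pop2$discrepancy <- rep(2, 8)
  expect_identical(check_stopping(pop2, cfg), "CONTINUE")
  # all within tolerance: matched (takes precedence over collapse)
  pop$discrepancy <- rep(0, 8)
  expect_identical(check_stopping(pop, cfg), "MATCHED")
})

test_that("the engine recovers a 1-D identifiable speed", {
  cand <- fixture_candidates("LOW")
  fwd <- scripted_forward()
  target <- scripted_target(50)
  cfg <- inference_config(population_size = 32, tolerance = 0.5,
                          max_iterations = 40, seed = 12,
                          kernel = list(sigma_endo = 5, sigma_myo = 2.5,
                                        root_change_prob = 0.2,
                                        move_radius_cm = 2))
  set.seed(cfg$seed)
  pop <- sample_prior_lhs(cand, cfg$population_size, cfg$seed)
  pop <- evaluate_population(pop, fwd, target, "ATM")
  for (it in 1:cfg$max_iterations) {
    if (check_stopping(pop, cfg) != "CONTINUE") break
    pop <- replacement_step(pop, fwd, target, "ATM", cfg, cand)
  }
  inferred <- aggregate_speeds(pop)[["fibre"]]
  # dense grid-search oracle over the 1-D parameter
  grid <- seq(25, 90, by = 0.01)
  oracle_best <- grid[which.min(abs(grid - 50))]
  expect_lt(abs(inferred - oracle_best) / oracle_best, 0.05)
})

test_that("full inference is seed-reproducible with monotone max discrepancy", {
  mesh <- fixture_mesh()
  cand <- fixture_candidates("LOW")
  target <- fixture_atm()
  epi_target <- extract_epicardial_map(target, mesh)
  cfg <- inference_config(population_size = 16, max_iterations = 4,
                          seed = 21)
  r1 <- run_inference(mesh, cand, epi_target, "ATM", cfg)
  r2 <- run_inference(mesh, cand, epi_target, "ATM", cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(lapply(r1$population$members, unclass),
                   lapply(r2$population$members, unclass))
  expect_true(all(diff(r1$trace$max) <= 1e-12))
  expect_length(r1$population$members, 16)
})

test_that("population CSV round trip preserves members", {
  cand <- fixture_candidates("LOW")
  pop <- sample_prior_lhs(cand, 8, seed = 8)
  pop$discrepancy <- runif(8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, tmp)
  pop2 <- read_population_csv(tmp)
  expect_equal(vapply(pop2$members, function(m) unclass(m$speeds), numeric(4)),
               vapply(pop$members, function(m) unclass(m$speeds), numeric(4)),
               tolerance = 1e-12)
  expect_identical(lapply(pop2$members, function(m) m$root_active),
                   lapply(pop$members, function(m) m$root_active))
})
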