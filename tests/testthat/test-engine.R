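test_that("no dispersal means no switches and a constant resource", {
  p <- sim_params(d = 0, max_generations = 200L)
  run <- run_simulation(p, seed = 101)
  expect_identical(nrow(run$events), 0L)
  expect_true(all(run$records$resource_optimum == 5))
  expect_true(all(run$records$switch_occurred == 0))
  expect_true(all(run$records$n_dispersers == 0))
})

test_that("deterministic limit: on-optimum, no mutation, no dispersal grows to K", {
  p <- sim_params(sigma_v = 0, d = 0, max_generations = 300L, K = 200L)
  run <- run_simulation(p, seed = 102)
  expect_identical(run$termination, "reached_cap")
  # survival probability is exactly 1 at the optimum: no deaths, so the
  # population is non-decreasing and saturates at K
  sz <- run$records$population_size
  expect_true(all(diff(sz) >= 0))
  expect_identical(tail(sz, 1), 200)
  expect_true(all(run$records$p_min == 5 & run$records$p_max == 5, na.rm = TRUE))
  expect_true(all(run$records$IS == 0))
})

test_that("runs are bit-identical for identical (params, seed)", {
  p <- sim_params(max_generations = 150L)
  r1 <- run_simulation(p, seed = 7)
  r2 <- run_simulation(p, seed = 7)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$termination, r2$termination)
  r3 <- run_simulation(p, seed = 8)
  expect_false(identical(r1$records, r3$records))
})

test_that("degenerate run controls behave", {
  p <- sim_params(max_generations = 0L)
  run <- run_simulation(p, seed = 1)
  expect_identical(nrow(run$records), 0L)
  expect_identical(run$termination, "reached_cap")
  expect_identical(run$final_generation, 0L)
  # a population forced far off-optimum dies immediately
  p2 <- sim_params(max_generations = 10L, d = 0, b = 0)
  run2 <- run_simulation(p2, seed = 2,
                         initial_phenotypes = rep(5 + 20 * 0.5, 30))
  expect_identical(run2$termination, "extinct")
  expect_identical(run2$final_generation, 1L)
  # stepping an extinct state errors
  st <- population_state(numeric(0), 5)
  expect_error(step_generation(st, sim_params()), "extinct")
})

test_that("population size never exceeds K and switches bottleneck", {
  p <- sim_params(max_generations = 400L, K = 100L)
  for (seed in c(11, 12, 13)) {
    run <- run_simulation(p, seed)
    expect_true(all(run$records$population_size <= 100))
    expect_identical(sum(run$records$switch_occurred),
                     as.numeric(nrow(run$events)))
    # after a switch the population is the founders alone
    sw <- run$records[run$records$switch_occurred == 1, ]
    expect_true(all(sw$population_size == sw$n_founders))
    expect_true(all(run$records$n_founders <= run$records$n_dispersers))
    # termination status consistent with the last record
    last <- tail(run$records$population_size, 1)
    expect_identical(run$termination == "extinct", last == 0)
  }
})

test_that("zero resource offset pins every event at distance zero", {
  p <- sim_params(delta_r = 0, max_generations = 300L)
  run <- run_simulation(p, seed = 21)
  expect_true(all(run$records$offered_optimum == 5))
  expect_true(all(run$records$resource_optimum == 5))
  if (nrow(run$events) > 0) {
    expect_true(all(run$events$standardized_distance == 0))
  }
})

test_that("establishment probability matches the 1-(1-S)^m oracle", {
  # m identical dispersers at standardized distance D establish with
  # probability 1 - (1 - exp(-D^2/2))^m; drive the full engine path with
  # d = 1, b = 0, delta_r = 0 so every generation is one colonization trial
  # of the whole population at a fixed distance.
  cases <- list(c(m = 5, D = 1.5), c(m = 12, D = 2), c(m = 3, D = 0.5))
  set.seed(55)
  for (cs in cases) {
    m <- cs[["m"]]; D <- cs[["D"]]
    p <- sim_params(d = 1, b = 0, sigma_v = 0, delta_r = 0,
                    max_generations = 1L)
    n_trials <- 4000L
    hits <- 0L
    for (i in seq_len(n_trials)) {
      st <- population_state(rep(5 + D * 0.5, m), 5)
      out <- step_generation(st, p)
      hits <- hits + (!is.null(out$event))
    }
    s1 <- exp(-D^2 / 2)
    expected <- 1 - (1 - s1)^m
    se <- sqrt(expected * (1 - expected) / n_trials)
    expect_lt(abs(hits / n_trials - expected), 3.5 * se)
  }
})

test_that("failed dispersers die under the lethal variant and return otherwise", {
  base <- list(d = 1, b = 0, sigma_v = 0, delta_r = 60, max_generations = 1L,
               n0 = 20L)
  # delta_r huge: the offered resource is essentially never colonizable and
  # the home optimum is matched exactly, so mortality on return is survival 1
  p_ret <- do.call(sim_params, base)
  p_die <- do.call(sim_params, c(base, list(failed_disperser_fate = "die")))
  r1 <- run_simulation(p_ret, seed = 3)
  r2 <- run_simulation(p_die, seed = 3)
  if (nrow(r1$events) == 0) {
    expect_identical(r1$records$population_size, 20)
  }
  if (nrow(r2$events) == 0) {
    expect_identical(r2$records$population_size, 0)
    expect_identical(r2$termination, "extinct")
  }
})

test_that("outcome classification follows the extinction-based rule", {
  ev <- data.frame(generation = c(60L, 110L, 300L),
                   outcome = "pending", resolution_generation = NA_integer_)
  extinct <- list(termination = "extinct", final_generation = 350L)
  capped <- list(termination = "reached_cap", final_generation = 1000L)
  out1 <- classify_outcomes(ev, extinct)
  expect_identical(out1$outcome, c("success", "success", "failure"))
  expect_identical(out1$resolution_generation, c(110L, 300L, 350L))
  out2 <- classify_outcomes(ev, capped)
  expect_identical(out2$outcome, rep("success", 3))
  expect_identical(out2$resolution_generation, c(110L, 300L, 1000L))
  # empty in, empty out
  empty <- ev[0, ]
  expect_identical(nrow(classify_outcomes(empty, capped)), 0L)
  # unordered events rejected
  expect_error(classify_outcomes(ev[c(2, 1, 3), ], capped), "ordered")
})

test_that("coupled-seed shift invariance holds for whole trajectories", {
  # shifting the initial optimum shifts every phenotype and optimum by the
  # same constant but leaves sizes, IS, distances, and events identical
  p1 <- sim_params(max_generations = 120L)
  p2 <- sim_params(max_generations = 120L, p_r0 = 5 + 3.25)
  r1 <- run_simulation(p1, seed = 77)
  r2 <- run_simulation(p2, seed = 77)
  expect_identical(r1$records$population_size, r2$records$population_size)
  expect_equal(r1$records$IS, r2$records$IS, tolerance = 1e-9)
  expect_equal(r2$records$resource_optimum - r1$records$resource_optimum,
               rep(3.25, nrow(r1$records)), tolerance = 1e-9)
  expect_equal(r1$events$standardized_distance,
               r2$events$standardized_distance, tolerance = 1e-9)
})
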