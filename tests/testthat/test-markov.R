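test_that("built-in models reproduce the published tables", {
  m1 <- builtin_model(1)
  expect_identical(m1$descriptors, paste0("D", 1:4))
  expect_equal(m1$initial, c(0.5, 0.25, 0.25, 0))
  expect_identical(m1$n_steps, 20L)
  expect_identical(vapply(m1$phases, function(p) p$first_step, 0L),
                   c(0L, 7L, 14L))
  # spot rows of the transition tables
  expect_equal(unname(m1$phases[[1]]$matrix["D4", ]), c(0, 0, 0.4, 0.6))
  expect_equal(unname(m1$phases[[1]]$matrix["D1", ]), c(0.5, 0.3, 0.2, 0))
  expect_equal(unname(m1$phases[[3]]$matrix["D4", ]), c(0.1, 0, 0.2, 0.7))

  m2 <- builtin_model(2)
  expect_equal(m2$initial, c(1 / 6, 1 / 3, 1 / 3, 1 / 6, 0, 0))
  expect_equal(unname(m2$phases[[3]]$matrix["D5", ]),
               c(0, 0, 0, 0.1, 0.6, 0.3))
  expect_equal(unname(m2$phases[[2]]$matrix["D2", ]),
               c(0, 0.3, 0.3, 0.2, 0.1, 0.1))

  expect_error(builtin_model(3), "case must be 1 or 2")
})

test_that("model validation flags broken specifications", {
  ok <- builtin_model(1)
  bad <- ok
  bad$initial <- c(0.5, 0.5, 0.2, 0)
  expect_error(validate_markov_tds_model(bad), "sum to 1")
  bad <- ok
  bad$phases[[2]]$matrix[2, 2] <- 0.9
  expect_error(validate_markov_tds_model(bad), "not stochastic")
  expect_error(markov_tds_model(ok$descriptors, ok$initial,
                                list(list(first_step = 1,
                                          matrix = ok$phases[[1]]$matrix)),
                                20),
               "start at step 0")
})

test_that("identity transitions freeze the initial draw", {
  model <- markov_tds_model(
    c("A", "B", "C"), c(0.2, 0.5, 0.3),
    list(list(first_step = 0L, matrix = diag(3))), n_steps = 10
  )
  set.seed(51)
  st <- simulate_trajectories(model, 200)
  expect_true(all(st == st[, 1]))
})

test_that("simulated draws match the model probabilities", {
  model <- builtin_model(1)
  set.seed(53)
  st <- simulate_trajectories(model, 100000)
  # initial distribution within 3 binomial standard errors
  freq0 <- tabulate(st[, 1], 4) / nrow(st)
  se0 <- sqrt(model$initial * (1 - model$initial) / nrow(st))
  expect_true(all(abs(freq0 - model$initial) <= pmax(3 * se0, 1e-6)))
  # one-step transitions out of D1 during the initial phase
  from_d1 <- st[st[, 1] == 1L, 2]
  freq1 <- tabulate(from_d1, 4) / length(from_d1)
  row <- unname(model$phases[[1]]$matrix["D1", ])
  se1 <- sqrt(row * (1 - row) / length(from_d1))
  expect_true(all(abs(freq1 - row) <= pmax(3.5 * se1, 1e-6)))
})

test_that("populations are reproducible and grid-complete", {
  model <- builtin_model(2)
  pop1 <- simulate_population(model, 40, seed = 57)
  pop2 <- simulate_population(model, 40, seed = 57)
  expect_equal(pop1, pop2)
  expect_error(simulate_population(model, 0), ">= 1")
  # every trajectory has n_steps + 1 states and converts losslessly
  set.seed(59)
  st <- simulate_trajectories(model, 25)
  expect_identical(dim(st), c(25L, 21L))
  for (i in 1:25) {
    task <- trajectory_to_task(st[i, ], model$descriptors, paste0("s", i))
    expect_identical(task_to_trajectory(task, model$descriptors, 20), st[i, ])
  }
})

test_that("exact marginals start at the initial distribution and conserve mass", {
  for (case in 1:2) {
    model <- builtin_model(case)
    em <- exact_marginals(model)
    expect_equal(unname(em$values[, 1]), model$initial)
    expect_equal(unname(colSums(em$values)), rep(1, 21), tolerance = 1e-14)
  }
  # one transition of Case 1, derived by enumerating (state0, state1) pairs
  em1 <- exact_marginals(builtin_model(1))
  expect_equal(unname(em1$values[, 2]), c(0.30, 0.325, 0.30, 0.075),
               tolerance = 1e-14)
})

test_that("exact marginals equal exhaustive path enumeration", {
  model <- truncated_case1(n_steps = 4, switch_step = 2)
  em <- exact_marginals(model)
  expect_equal(em$values, enumerate_marginals(model), tolerance = 1e-12)
})

test_that("empirical curves converge to the exact marginals", {
  model <- builtin_model(1)
  set.seed(61)
  pop <- simulate_population(model, 10000)
  cv <- compute_curves(pop, model$descriptors, time_grid(21))
  em <- exact_marginals(model)
  expect_lt(max(abs(cv$values - em$values)), 4 * sqrt(0.25 / 10000))
  # simulated tasks always start selected, so columns sum to 1
  expect_equal(unname(colSums(cv$values)), rep(1, 21), tolerance = 1e-9)
})
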