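test_that("resample_tasks draws uniformly with replacement", {
  t1 <- tds_task("only", 0, 1, data.frame(time = 0, descriptor = "D1"))
  expect_identical(resample_tasks(list(t1)), list(t1))
  expect_error(resample_tasks(list()), "empty")

  set.seed(71)
  m <- 50
  tasks <- random_tasks(m)
  reps <- 2000
  absent <- 0
  mult1 <- 0
  for (r in seq_len(reps)) {
    ids <- vapply(resample_tasks(tasks), function(x) x$task_id, "")
    expect_length(ids, m)
    absent <- absent + !("t001" %in% ids)
    mult1 <- mult1 + sum(ids == "t001")
  }
  # chance a given task misses one resample: (1 - 1/m)^m; expected
  # multiplicity of each task is 1
  p_absent <- (1 - 1 / m)^m
  expect_lt(abs(absent / reps - p_absent),
            4 * sqrt(p_absent * (1 - p_absent) / reps))
  expect_lt(abs(mult1 / reps - 1), 0.1)
})

test_that("bootstrap replicates center on the base curves", {
  one <- tds_task("same", 0, 1, data.frame(time = c(0, 0.4),
                                           descriptor = c("D1", "D2")))
  ens <- bootstrap_curves(rep(list(one), 20), c("D1", "D2"),
                          time_grid(9), q = 50)
  for (r in 1:50) {
    expect_equal(unname(ens$replicates[r, , ]),
                 unname(ens$base_curves$values))
  }

  set.seed(73)
  pop <- simulate_population(builtin_model(1), 100)
  ens <- bootstrap_curves(pop, builtin_model(1)$descriptors,
                          time_grid(21), q = 1000)
  rep_mean <- apply(ens$replicates, c(2, 3), mean)
  expect_lt(max(abs(rep_mean - ens$base_curves$values)), 0.02)
})

test_that("replicate spread matches the binomial sampling variance", {
  set.seed(79)
  model <- builtin_model(1)
  pop <- simulate_population(model, 100)
  ens <- bootstrap_curves(pop, model$descriptors, time_grid(21), q = 1000)
  d <- ens$base_curves$values
  sd_emp <- apply(ens$replicates, c(2, 3), sd)
  sd_theory <- sqrt(d * (1 - d) / 100)
  mid <- d >= 0.3 & d <= 0.7
  expect_true(any(mid))
  expect_lt(max(abs(sd_emp[mid] / sd_theory[mid] - 1)), 0.1)
})

test_that("order-statistic bands index the sorted replicate values exactly", {
  set.seed(83)
  p <- 2; G <- 5; q <- 1000
  # one point carries a known permutation of 1..1000 (scaled)
  flat <- matrix(runif(q * p * G), nrow = q)
  flat[, 1] <- sample(seq_len(q)) / q
  ens <- tdsboot:::new_tds_bootstrap(
    compute_curves(list(tds_task("x", 0, 1,
                                 data.frame(time = 0, descriptor = "A"))),
                   c("A", "B"), time_grid(G)),
    flat, c("A", "B"), time_grid(G), q, m = 10)
  ci <- band_from_order_statistics(ens, "ci95")
  se <- band_from_order_statistics(ens, "se")
  expect_equal(unname(ci$lower[1, 1]), 25 / q)
  expect_equal(unname(ci$upper[1, 1]), 976 / q)
  expect_equal(unname(se$lower[1, 1]), 159 / q)
  expect_equal(unname(se$upper[1, 1]), 842 / q)
  # full-sort oracle across every point (flat columns are descriptor-fastest,
  # the same order as column-major p x G matrices)
  for (band in list(list(b = ci, k = 25), list(b = se, k = 159))) {
    oracle <- naive_order_band(flat, band$k)
    expect_equal(as.vector(band$b$lower), unname(oracle$lower))
    expect_equal(as.vector(band$b$upper), unname(oracle$upper))
  }
})

test_that("order-statistic bands match the full-sort oracle on small ensembles", {
  set.seed(89)
  for (q in c(41, 50)) {
    flat <- matrix(runif(q * 12), nrow = q)
    ens <- tdsboot:::new_tds_bootstrap(NULL, flat, paste0("D", 1:3),
                                       time_grid(4), q, m = 7)
    for (band in c("ci95", "se")) {
      got <- band_from_order_statistics(ens, band)
      k <- tdsboot:::band_rank(band, q)
      oracle <- naive_order_band(flat, k)
      expect_equal(as.vector(got$lower), unname(oracle$lower))
      expect_equal(as.vector(got$upper), unname(oracle$upper))
      expect_true(all(got$lower <= got$upper))
    }
  }
  # degenerate ensemble: identical replicates give zero-width bands
  flat0 <- matrix(0.4, nrow = 50, ncol = 6)
  ens0 <- tdsboot:::new_tds_bootstrap(NULL, flat0, c("A", "B"),
                                      time_grid(3), 50, m = 5)
  b0 <- band_from_order_statistics(ens0, "ci95")
  expect_true(all(b0$upper - b0$lower == 0))
  # too few replicates for the requested rank
  ens_small <- tdsboot:::new_tds_bootstrap(NULL, flat0[1:10, ], c("A", "B"),
                                           time_grid(3), 10, m = 5)
  expect_error(band_from_order_statistics(ens_small, "ci95"), "increase q")
})

test_that("normal-approximation bands follow the proportion formula", {
  cv <- tdsboot:::new_tds_curves(
    matrix(c(0.5, 0, 1, 0.2), nrow = 1,
           dimnames = list("D1", NULL)),
    c(0, 1 / 3, 2 / 3, 1), 100L)
  ci <- normal_bands(cv, m = 100, band = "ci95")
  expect_equal(unname(ci$lower[1, 1]), 0.5 - 1.96 * sqrt(0.25 / 100))
  expect_equal(unname(ci$upper[1, 1]), 0.5 + 1.96 * sqrt(0.25 / 100))
  # degenerate proportions give zero-width, flagged intervals
  expect_equal(unname(ci$lower[1, 2]), 0)
  expect_equal(unname(ci$upper[1, 2]), 0)
  expect_equal(unname(ci$upper[1, 3] - ci$lower[1, 3]), 0)
  expect_true(ci$flags[1, 2] && ci$flags[1, 3])
  expect_false(ci$flags[1, 1])
  se <- normal_bands(cv, m = 100, band = "se")
  expect_equal(unname(se$upper[1, 1] - se$lower[1, 1]), 0.1)  # halfwidth 0.05
  # clipping to [0, 1] is recorded
  cv2 <- tdsboot:::new_tds_curves(
    matrix(0.02, nrow = 1, dimnames = list("D1", NULL)),
    c(0, 1), 50L)
  b2 <- normal_bands(cv2, m = 50, band = "ci95")
  expect_gte(min(b2$lower), 0)
  expect_true(all(b2$clipped))
})

test_that("the CI95 band contains the SE band everywhere", {
  set.seed(97)
  model <- builtin_model(2)
  pop <- simulate_population(model, 80)
  ens <- bootstrap_curves(pop, model$descriptors, time_grid(21), q = 1000)
  ci <- band_from_order_statistics(ens, "ci95")
  se <- band_from_order_statistics(ens, "se")
  expect_true(all(ci$lower <= se$lower + 1e-12))
  expect_true(all(se$upper <= ci$upper + 1e-12))
  cv <- ens$base_curves
  nci <- normal_bands(cv, 80, "ci95")
  nse <- normal_bands(cv, 80, "se")
  expect_true(all(nci$lower <= nse$lower + 1e-12))
  expect_true(all(nse$upper <= nci$upper + 1e-12))
})

test_that("larger samples give narrower bootstrap bands", {
  model <- builtin_model(1)
  set.seed(101)
  pop <- simulate_population(model, 400)
  widths <- vapply(c(50, 100, 200), function(m) {
    ens <- bootstrap_curves(pop[seq_len(m)], model$descriptors,
                            time_grid(21), q = 500)
    b <- band_from_order_statistics(ens, "ci95")
    mean(b$upper - b$lower)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap and normal CI halfwidths agree for large samples", {
  model <- builtin_model(1)
  set.seed(103)
  pop <- simulate_population(model, 500)
  ens <- bootstrap_curves(pop, model$descriptors, time_grid(21), q = 1000)
  boot <- band_from_order_statistics(ens, "ci95")
  norm <- normal_bands(ens$base_curves, 500, "ci95")
  d <- ens$base_curves$values
  mid <- d >= 0.2 & d <= 0.8
  expect_true(any(mid))
  hb <- (boot$upper - boot$lower)[mid] / 2
  hn <- 1.96 * sqrt(d[mid] * (1 - d[mid]) / 500)
  expect_lt(max(abs(hb / hn - 1)), 0.15)
})
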