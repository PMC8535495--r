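# Generators and independent oracles used across the suite.
# All draw from the session RNG; callers set.seed() first.

# A random valid task; raw = TRUE gives arbitrary start/stop times,
# otherwise the task is already on [0, 1]. Always has >= 1 event.
random_task <- function(id, p = 4, max_events = 6, raw = FALSE) {
  start <- if (raw) runif(1, 0, 50) else 0
  dur <- if (raw) runif(1, 1, 120) else 1
  stop <- start + dur
  n_ev <- sample.int(max_events, 1)
  times <- sort(start + dur * runif(n_ev))
  # occasionally anchor the first event at the start instant
  if (runif(1) < 0.5) times[1] <- start
  tds_task(id, start, stop,
           data.frame(time = times,
                      descriptor = paste0("D", sample.int(p, n_ev,
                                                          replace = TRUE))))
}

random_tasks <- function(n, ...) {
  lapply(seq_len(n), function(i) random_task(sprintf("t%03d", i), ...))
}

# Brute-force dominance indicator: linear scan of the event list.
brute_indicator <- function(task, descriptor, t) {
  ev <- task$events
  current <- NA_character_
  for (r in seq_len(nrow(ev))) {
    if (ev$time[r] <= t) current <- ev$descriptor[r] else break
  }
  as.integer(!is.na(current) && current == descriptor)
}

# Exhaustive path-enumeration oracle for the marginal state distribution of
# a Markov TDS model: sums initial x transition products over all
# p^(n_steps+1) state paths. Only feasible for tiny models.
enumerate_marginals <- function(model) {
  p <- length(model$descriptors)
  G <- model$n_steps + 1L
  paths <- as.matrix(expand.grid(rep(list(seq_len(p)), G)))
  prob <- model$initial[paths[, 1]]
  for (k in seq_len(model$n_steps)) {
    M <- tdsboot:::step_matrix(model, k - 1L)
    prob <- prob * M[cbind(paths[, k], paths[, k + 1L])]
  }
  vals <- matrix(0, nrow = p, ncol = G,
                 dimnames = list(model$descriptors, NULL))
  for (k in seq_len(G)) {
    for (j in seq_len(p)) vals[j, k] <- sum(prob[paths[, k] == j])
  }
  vals
}

# Case 1 matrices on a short timeline with a phase switch, small enough for
# exhaustive enumeration.
truncated_case1 <- function(n_steps = 4, switch_step = 2) {
  m <- builtin_model(1)
  markov_tds_model(
    descriptors = m$descriptors,
    initial = m$initial,
    phases = list(
      list(first_step = 0L, matrix = m$phases[[1]]$matrix),
      list(first_step = as.integer(switch_step),
           matrix = m$phases[[2]]$matrix)
    ),
    n_steps = n_steps
  )
}

# Full-sort order-statistic oracle: k-th smallest and k-th largest of each
# point's replicate values, taken literally from the sorted vector.
naive_order_band <- function(flat, k) {
  lo <- apply(flat, 2, function(v) sort(v)[k])
  hi <- apply(flat, 2, function(v) rev(sort(v))[k])
  list(lower = lo, upper = hi)
}
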