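#' Phase-dependent Markov model of a TDS task
#'
#' Descriptors are states of a discrete-time Markov chain on the normalized
#' timeline. A task starts in a state drawn from `initial`, then makes
#' `n_steps` transitions of width `1/n_steps`. The transition table in force
#' can change along the timeline: the chain's period is partitioned into
#' phases, each owning a row-stochastic p x p matrix. The transition leaving
#' grid point `k/n_steps` uses the table of the phase containing that
#' *source* time, so a phase starting at step `s` governs transitions leaving
#' steps `s, s+1, ...` up to the next phase.
#'
#' @param descriptors Ordered character vector of p state labels.
#' @param initial Probability vector of length p (sums to 1).
#' @param phases List of phases, each `list(first_step = <0-based step
#'   index>, matrix = <p x p row-stochastic matrix>)`; `first_step`s strictly
#'   increasing, the first equal to 0.
#' @param n_steps Transitions per task (the built-in cases use 20).
#' @return An object of class `markov_tds_model`.
#' @export
markov_tds_model <- function(descriptors, initial, phases, n_steps) {
  x <- structure(
    list(
      descriptors = as.character(descriptors),
      initial = as.numeric(initial),
      phases = lapply(phases, function(ph) {
        list(first_step = as.integer(ph$first_step),
             matrix = as.matrix(ph$matrix))
      }),
      n_steps = as.integer(n_steps)
    ),
    class = "markov_tds_model"
  )
  validate_markov_tds_model(x)
}

#' @rdname markov_tds_model
#' @param x A `markov_tds_model`.
#' @export
validate_markov_tds_model <- function(x) {
  p <- length(x$descriptors)
  tol <- 1e-9
  if (p < 1) stop("model needs at least one descriptor", call. = FALSE)
  if (length(x$initial) != p) {
    stop("initial distribution length ", length(x$initial),
         " does not match ", p, " descriptors", call. = FALSE)
  }
  if (any(x$initial < 0) || abs(sum(x$initial) - 1) > tol) {
    stop("initial distribution must be non-negative and sum to 1 (sum = ",
         format(sum(x$initial), digits = 12), ")", call. = FALSE)
  }
  if (x$n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  firsts <- vapply(x$phases, function(ph) ph$first_step, 0L)
  if (length(firsts) == 0 || firsts[1] != 0L) {
    stop("the first phase must start at step 0", call. = FALSE)
  }
  if (any(diff(firsts) <= 0)) {
    stop("phase first_steps must be strictly increasing", call. = FALSE)
  }
  if (any(firsts >= x$n_steps)) {
    stop("phase first_steps must be < n_steps", call. = FALSE)
  }
  for (i in seq_along(x$phases)) {
    M <- x$phases[[i]]$matrix
    if (!all(dim(M) == c(p, p))) {
      stop("phase ", i, ": transition matrix must be ", p, " x ", p,
           call. = FALSE)
    }
    rs <- rowSums(M)
    bad <- which(abs(rs - 1) > tol | apply(M < 0, 1, any))
    if (length(bad) > 0) {
      stop("phase ", i, ": row(s) ",
           paste(x$descriptors[bad], collapse = ", "),
           " not stochastic (sums ",
           paste(format(rs[bad], digits = 12), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  x
}

#' @export
print.markov_tds_model <- function(x, ...) {
  cat(sprintf("<markov_tds_model> %d descriptors (%s), %d transitions, %d phase(s) at step(s) %s\n",
              length(x$descriptors), paste(x$descriptors, collapse = ", "),
              x$n_steps,
              length(x$phases),
              paste(vapply(x$phases, function(p) p$first_step, 0L),
                    collapse = ", ")))
  cat("initial:", format(x$initial, digits = 4), "\n")
  invisible(x)
}

# matrix in force for the transition leaving 0-based step k, k in 0..n_steps-1
step_matrix <- function(model, k) {
  firsts <- vapply(model$phases, function(ph) ph$first_step, 0L)
  model$phases[[findInterval(k, firsts)]]$matrix
}

#' Built-in Markov TDS models
#'
#' Two reference models with 20 transitions and three phases (initial phase
#' governing transitions leaving steps 0-6, middle 7-13, last 14-19):
#'
#' * **Case 1** — 4 descriptors, initial distribution
#'   (0.5, 0.25, 0.25, 0).
#' * **Case 2** — 6 descriptors, initial distribution
#'   (1/6, 1/3, 1/3, 1/6, 0, 0), stored as exact double-precision quotients.
#'
#' In the published Case 2 last-phase table the row leaving D3 is not
#' row-stochastic as printed (entries sum to 1.1); it is corrected here by
#' the minimal edit D3->D4 0.4 -> 0.3 so the chain is well defined.
#'
#' @param case 1 or 2.
#' @return A [markov_tds_model()].
#' @examples
#' builtin_model(1)
#' @export
builtin_model <- function(case) {
  if (!(length(case) == 1 && case %in% c(1, 2))) {
    stop("case must be 1 or 2", call. = FALSE)
  }
  if (case == 1) {
    d <- paste0("D", 1:4)
    init <- c(0.5, 0.25, 0.25, 0)
    M_init <- matrix(c(
      0.5, 0.3, 0.2, 0,
      0.1, 0.5, 0.3, 0.1,
      0.1, 0.2, 0.5, 0.2,
      0,   0,   0.4, 0.6), 4, 4, byrow = TRUE)
    M_mid <- matrix(c(
      0.4, 0.3, 0.2, 0.1,
      0.1, 0.4, 0.3, 0.2,
      0.1, 0.1, 0.6, 0.2,
      0.1, 0.1, 0.2, 0.6), 4, 4, byrow = TRUE)
    M_last <- matrix(c(
      0.2, 0.2, 0.3, 0.3,
      0.1, 0.3, 0.3, 0.3,
      0.1, 0.2, 0.3, 0.4,
      0.1, 0,   0.2, 0.7), 4, 4, byrow = TRUE)
  } else {
    d <- paste0("D", 1:6)
    init <- c(1 / 6, 1 / 3, 1 / 3, 1 / 6, 0, 0)
    M_init <- matrix(c(
      0.4, 0.3, 0.2, 0.1, 0,   0,
      0.1, 0.4, 0.2, 0.2, 0.1, 0,
      0.1, 0.2, 0.4, 0.2, 0,   0.1,
      0,   0.1, 0.4, 0.3, 0.1, 0.1,
      0,   0,   0.3, 0.2, 0.3, 0.2,
      0,   0,   0.2, 0.2, 0.3, 0.3), 6, 6, byrow = TRUE)
    M_mid <- matrix(c(
      0.3, 0.3, 0.2, 0.1, 0.1, 0,
      0,   0.3, 0.3, 0.2, 0.1, 0.1,
      0.1, 0.1, 0.4, 0.3, 0.1, 0,
      0,   0.1, 0.2, 0.4, 0.2, 0.1,
      0,   0,   0.1, 0.2, 0.3, 0.4,
      0,   0,   0.1, 0.2, 0.3, 0.4), 6, 6, byrow = TRUE)
    # row D3 corrected for stochasticity (see Details)
    M_last <- matrix(c(
      0.1, 0.2, 0.3, 0.3, 0.1, 0,
      0.1, 0.3, 0.3, 0.3, 0,   0,
      0.1, 0.2, 0.3, 0.3, 0.1, 0,
      0.1, 0,   0.2, 0.5, 0.2, 0,
      0,   0,   0,   0.1, 0.6, 0.3,
      0,   0,   0.1, 0.1, 0.3, 0.5), 6, 6, byrow = TRUE)
  }
  dimnames(M_init) <- dimnames(M_mid) <- dimnames(M_last) <- list(d, d)
  markov_tds_model(
    descriptors = d,
    initial = init,
    phases = list(
      list(first_step = 0L, matrix = M_init),
      list(first_step = 7L, matrix = M_mid),
      list(first_step = 14L, matrix = M_last)
    ),
    n_steps = 20L
  )
}

#' Simulate trajectories from a Markov TDS model
#'
#' Draws `n` independent state sequences, each of length `n_steps + 1` (one
#' state per grid point `k/n_steps`). Randomness comes from R's global RNG
#' stream; draws are consumed in a fixed order (all initial states first,
#' then all transitions step by step along the timeline), so a population is
#' bit-reproducible after `set.seed()`.
#'
#' @param model A [markov_tds_model()].
#' @param n Number of trajectories (>= 1).
#' @return Integer matrix `n x (n_steps + 1)` of 1-based state indices.
#' @export
simulate_trajectories <- function(model, n) {
  stopifnot(inherits(model, "markov_tds_model"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  p <- length(model$descriptors)
  G <- model$n_steps + 1L
  states <- matrix(0L, nrow = n, ncol = G)
  states[, 1] <- draw_categorical(n, model$initial)
  for (k in seq_len(model$n_steps)) {
    M <- step_matrix(model, k - 1L)
    cm <- t(apply(M, 1, cumsum))
    cm[, p] <- 1  # guard against accumulated float error in the last column
    u <- stats::runif(n)
    states[, k + 1L] <- 1L + as.integer(
      rowSums(u > cm[states[, k], , drop = FALSE]))
  }
  states
}

draw_categorical <- function(n, prob) {
  cm <- cumsum(prob)
  cm[length(cm)] <- 1
  1L + as.integer(findInterval(stats::runif(n), cm,
                               left.open = TRUE, rightmost.closed = TRUE))
}

#' @rdname simulate_trajectories
#' @return `simulate_task` returns a single trajectory as an integer vector.
#' @export
simulate_task <- function(model) {
  as.integer(simulate_trajectories(model, 1L)[1, ])
}

#' Convert between trajectories and task records
#'
#' A trajectory places the chain's state at each grid point; the equivalent
#' task record has `start = 0`, `stop = 1` and one selection event at `t' =
#' k/n_steps` for the initial state and each state change. The conversion is
#' lossless for sequences observed on the native grid.
#'
#' @param trajectory Integer vector of 1-based state indices, length
#'   `n_steps + 1`.
#' @param descriptors State labels.
#' @param task_id Identifier for the resulting record.
#' @return `trajectory_to_task` returns a [tds_task()];
#'   `task_to_trajectory` returns an integer vector.
#' @export
trajectory_to_task <- function(trajectory, descriptors, task_id = "sim") {
  n_steps <- length(trajectory) - 1L
  stopifnot(n_steps >= 1, all(trajectory >= 1),
            all(trajectory <= length(descriptors)))
  change <- c(TRUE, diff(trajectory) != 0)
  tds_task(
    task_id, 0, 1,
    data.frame(
      time = (which(change) - 1L) / n_steps,
      descriptor = descriptors[trajectory[change]]
    )
  )
}

#' @rdname trajectory_to_task
#' @param task A normalized [tds_task()] with an event at `t' = 0`.
#' @param n_steps Number of transitions of the native grid.
#' @export
task_to_trajectory <- function(task, descriptors, n_steps) {
  states <- task_state_matrix(list(task), descriptors,
                              seq(0, 1, length.out = n_steps + 1L))[1, ]
  if (any(states == 0L)) {
    stop("task ", task$task_id, " has no selection at t' = 0; ",
         "it did not come from a grid trajectory", call. = FALSE)
  }
  as.integer(states)
}

#' Simulate a population of TDS tasks
#'
#' Draws `n` independent tasks from the model and returns them as task
#' records on the normalized timeline (the population of a Monte Carlo
#' experiment).
#'
#' @inheritParams simulate_trajectories
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @param id_prefix Prefix for generated task identifiers.
#' @return List of `n` [tds_task()] records.
#' @examples
#' pop <- simulate_population(builtin_model(1), 50, seed = 1)
#' compute_curves(pop, builtin_model(1)$descriptors, time_grid(21))
#' @export
simulate_population <- function(model, n, seed = NULL, id_prefix = "sim") {
  if (!is.null(seed)) set.seed(seed)
  states <- simulate_trajectories(model, n)
  ids <- sprintf("%s%0*d", id_prefix, nchar(as.character(n)), seq_len(n))
  lapply(seq_len(n), function(i) {
    trajectory_to_task(states[i, ], model$descriptors, ids[i])
  })
}

#' Exact population dominance proportions of a Markov TDS model
#'
#' The marginal state distribution at grid point k is the initial
#' distribution propagated through the first k transition matrices:
#' `initial %*% M_0 %*% ... %*% M_{k-1}`. These are the dominance
#' proportions an infinite simulated population would show, and serve as the
#' analytic oracle for the simulator.
#'
#' @param model A [markov_tds_model()].
#' @return A `tds_curves` object on the native `n_steps + 1` grid with
#'   `n_tasks = Inf`; columns sum to exactly 1.
#' @export
exact_marginals <- function(model) {
  stopifnot(inherits(model, "markov_tds_model"))
  p <- length(model$descriptors)
  G <- model$n_steps + 1L
  values <- matrix(0, nrow = p, ncol = G,
                   dimnames = list(model$descriptors, NULL))
  v <- model$initial
  values[, 1] <- v
  for (k in seq_len(model$n_steps)) {
    v <- as.vector(v %*% step_matrix(model, k - 1L))
    values[, k + 1L] <- v
  }
  new_tds_curves(values, seq(0, 1, length.out = G), Inf)
}

#' Read / write a Markov TDS model specification
#'
#' Model files hold `descriptors`, `initial`, `phases` (each with
#' `first_step` and `matrix`) and `n_steps`, as JSON or YAML (by extension;
#' YAML needs the `yaml` package). Files are validated on load with
#' per-row stochasticity diagnostics.
#'
#' @param model A [markov_tds_model()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_model` returns a validated [markov_tds_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "markov_tds_model"))
  obj <- list(
    descriptors = model$descriptors,
    initial = model$initial,
    phases = lapply(model$phases, function(ph) {
      list(first_step = ph$first_step,
           matrix = apply(ph$matrix, 1, as.numeric, simplify = FALSE))
    }),
    n_steps = model$n_steps
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    requireNamespace("yaml")
    writeLines(yaml::as.yaml(obj), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    requireNamespace("yaml")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  descriptors <- unlist(obj$descriptors)
  markov_tds_model(
    descriptors = descriptors,
    initial = unlist(obj$initial),
    phases = lapply(obj$phases, function(ph) {
      M <- do.call(rbind, lapply(ph$matrix, unlist))
      dimnames(M) <- list(descriptors, descriptors)
      list(first_step = ph$first_step, matrix = M)
    }),
    n_steps = obj$n_steps
  )
}
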