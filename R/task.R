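#' Construct a TDS task record
#'
#' A temporal dominance of sensations (TDS) task is one assessor's run over
#' one sample: the assessor presses start, sequentially selects the single
#' dominant descriptor (each selection stays in force until the next press),
#' and presses stop. The record keeps the start/stop instants and the ordered
#' selection events.
#'
#' Event times must be strictly increasing and lie in `[start_time,
#' stop_time]`. A selection exactly at the stop instant is permitted — it is
#' how a state change landing on the final grid point of a simulated
#' trajectory is recorded — and is the dominant descriptor at `t' = 1`.
#' Re-selecting the descriptor that is already dominant is permitted and has
#' no effect on the induced indicator functions. Tasks may begin with a gap
#' before the first selection (no descriptor dominant); simulated tasks never
#' do, but panel data can.
#'
#' @param task_id Identifier, coerced to character.
#' @param start_time,stop_time Task boundaries in seconds (or any common
#'   unit); `stop_time > start_time`.
#' @param events A data frame with columns `time` and `descriptor`, or a
#'   two-column list coercible to one. May have zero rows.
#' @return An object of class `tds_task`.
#' @examples
#' tds_task("a01", 0, 10, data.frame(
#'   time = c(0, 4.2), descriptor = c("sweet", "bitter")))
#' @export
tds_task <- function(task_id, start_time, stop_time, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), descriptor = character(0))
  }
  events <- as.data.frame(events)
  if (!all(c("time", "descriptor") %in% names(events))) {
    stop("`events` needs columns `time` and `descriptor`", call. = FALSE)
  }
  events <- data.frame(
    time = as.numeric(events$time),
    descriptor = as.character(events$descriptor),
    stringsAsFactors = FALSE
  )
  x <- structure(
    list(
      task_id = as.character(task_id)[1],
      start_time = as.numeric(start_time)[1],
      stop_time = as.numeric(stop_time)[1],
      events = events
    ),
    class = "tds_task"
  )
  validate_tds_task(x)
}

#' @rdname tds_task
#' @param x A `tds_task`.
#' @export
validate_tds_task <- function(x) {
  id <- x$task_id
  if (!is.finite(x$start_time) || !is.finite(x$stop_time)) {
    stop("task ", id, ": start/stop times must be finite", call. = FALSE)
  }
  if (x$stop_time <= x$start_time) {
    stop("task ", id, ": degenerate record, stop_time must exceed start_time",
         call. = FALSE)
  }
  ev <- x$events
  if (nrow(ev) > 0) {
    if (anyNA(ev$time) || anyNA(ev$descriptor)) {
      stop("task ", id, ": missing event time or descriptor", call. = FALSE)
    }
    if (any(diff(ev$time) <= 0)) {
      stop("task ", id, ": event times must be strictly increasing",
           call. = FALSE)
    }
    if (ev$time[1] < x$start_time) {
      stop("task ", id, ": event at ", ev$time[1], " precedes start_time",
           call. = FALSE)
    }
    if (ev$time[nrow(ev)] > x$stop_time) {
      stop("task ", id, ": event after stop_time", call. = FALSE)
    }
  }
  x
}

#' @export
print.tds_task <- function(x, ...) {
  cat(sprintf("<tds_task> %s: [%g, %g], %d event(s)\n",
              x$task_id, x$start_time, x$stop_time, nrow(x$events)))
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}

#' Rescale a task to the normalized timeline
#'
#' TDS curves are aggregated on a common normalized timeline in which the
#' elapsed time between the start and stop presses equals 1. This affinely
#' maps a task onto `[0, 1]`, preserving event order.
#'
#' @param task A [tds_task()].
#' @return A `tds_task` with `start_time = 0`, `stop_time = 1` and rescaled
#'   event times.
#' @export
normalize_task <- function(task) {
  stopifnot(inherits(task, "tds_task"))
  dur <- task$stop_time - task$start_time
  if (!is.finite(dur) || dur <= .tds_tol) {
    stop("task ", task$task_id, ": degenerate record, zero duration",
         call. = FALSE)
  }
  if (abs(task$start_time) <= .tds_tol && abs(task$stop_time - 1) <= .tds_tol) {
    return(task)
  }
  ev <- task$events
  ev$time <- (ev$time - task$start_time) / dur
  task$start_time <- 0
  task$stop_time <- 1
  task$events <- ev
  validate_tds_task(task)
}

is_normalized_task <- function(task) {
  abs(task$start_time) <= .tds_tol && abs(task$stop_time - 1) <= .tds_tol
}

.tds_tol <- 1e-12

#' Dominance indicator of a descriptor at a normalized time
#'
#' Evaluates the binary step function induced by a normalized task: 1 if
#' `descriptor` is the most recent selection at or before `t_prime`, else 0.
#' Dominance intervals are right-open: at the exact instant of a selection the
#' newly selected descriptor is dominant, and the last selection persists
#' through `t_prime = 1`. Before the first selection every indicator is 0.
#'
#' @param task A normalized [tds_task()] (see [normalize_task()]).
#' @param descriptor A descriptor label present in `descriptors`.
#' @param t_prime Numeric vector of normalized times in `[0, 1]`.
#' @param descriptors Optional character vector of valid labels; defaults to
#'   the labels appearing in the task. Querying a label outside this set is
#'   an error (it usually indicates a typo, not a zero).
#' @return Integer vector of 0/1 values, one per `t_prime`.
#' @export
indicator <- function(task, descriptor, t_prime, descriptors = NULL) {
  stopifnot(inherits(task, "tds_task"))
  if (!is_normalized_task(task)) {
    stop("indicator() expects a normalized task; call normalize_task() first",
         call. = FALSE)
  }
  known <- if (is.null(descriptors)) unique(task$events$descriptor) else descriptors
  if (!descriptor %in% known) {
    stop("unknown descriptor label: ", descriptor, call. = FALSE)
  }
  if (any(t_prime < -.tds_tol | t_prime > 1 + .tds_tol)) {
    stop("t_prime must lie in [0, 1]", call. = FALSE)
  }
  ev <- task$events
  if (nrow(ev) == 0) return(integer(length(t_prime)))
  # largest event index with time <= t': right-open step semantics
  idx <- findInterval(t_prime, ev$time)
  out <- integer(length(t_prime))
  sel <- idx > 0
  out[sel] <- as.integer(ev$descriptor[idx[sel]] == descriptor)
  out
}

#' Descriptor labels used by a set of tasks
#'
#' Labels in order of first appearance across the task list.
#'
#' @param tasks A list of [tds_task()] records.
#' @return Character vector of labels.
#' @export
task_descriptors <- function(tasks) {
  unique(unlist(lapply(tasks, function(x) x$events$descriptor),
                use.names = FALSE))
}

# State of each task at each grid point: integer matrix n x |grid|,
# entry = descriptor index (match against `descriptors`), 0 = none selected.
task_state_matrix <- function(tasks, descriptors, grid) {
  n <- length(tasks)
  out <- matrix(0L, nrow = n, ncol = length(grid))
  for (i in seq_len(n)) {
    task <- tasks[[i]]
    if (!is_normalized_task(task)) {
      stop("task ", task$task_id, " is not normalized; call normalize_task()",
           call. = FALSE)
    }
    ev <- task$events
    if (nrow(ev) == 0) next
    j <- match(ev$descriptor, descriptors)
    if (anyNA(j)) {
      stop("task ", task$task_id, ": descriptor(s) ",
           paste(unique(ev$descriptor[is.na(j)]), collapse = ", "),
           " not in `descriptors`", call. = FALSE)
    }
    idx <- findInterval(grid, ev$time)
    sel <- idx > 0
    out[i, sel] <- j[idx[sel]]
  }
  out
}

# One-hot expansion of a state matrix: n x (p * |grid|) with column
# (k - 1) * p + j holding the indicator of descriptor j at grid point k.
state_onehot <- function(states, p) {
  n <- nrow(states)
  G <- ncol(states)
  out <- matrix(0, nrow = n, ncol = p * G)
  k <- rep(seq_len(G), each = n)
  i <- rep(seq_len(n), times = G)
  s <- as.vector(states)
  keep <- s > 0L
  out[cbind(i[keep], (k[keep] - 1L) * p + s[keep])] <- 1
  out
}
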