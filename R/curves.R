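#' Evaluation grid on the normalized timeline
#'
#' An ordered vector of normalized times spanning `[0, 1]`. Real panel data
#' are conventionally evaluated on 101 evenly spaced points; tasks simulated
#' from the built-in Markov models live natively on 21 points (20 transitions
#' of width 1/20).
#'
#' @param n_points Number of evenly spaced points (>= 2).
#' @return Numeric vector of strictly increasing times, first 0, last 1.
#' @export
time_grid <- function(n_points = 101) {
  stopifnot(n_points >= 2)
  seq(0, 1, length.out = n_points)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2) {
    stop("grid must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("grid points must be strictly increasing", call. = FALSE)
  }
  if (abs(grid[1]) > .tds_tol || abs(grid[length(grid)] - 1) > .tds_tol) {
    stop("grid must start at 0 and end at 1", call. = FALSE)
  }
  grid
}

new_tds_curves <- function(values, grid, n_tasks) {
  structure(
    list(values = values, grid = grid, n_tasks = n_tasks),
    class = "tds_curves"
  )
}

#' Compute TDS curves (dominance proportions)
#'
#' For each descriptor j and grid point t', the dominance proportion is the
#' fraction of tasks whose indicator for j equals 1 at t':
#' \deqn{d_j(t') = \frac{1}{n}\sum_{i=1}^{n} b_{ij}(t').}
#' Proportions are taken over all `n` tasks; tasks that have made no selection
#' yet contribute 0 to every descriptor, so column sums may fall below 1
#' before the first selections (they equal 1 wherever every task has selected
#' something, as simulated tasks always have).
#'
#' @param tasks Non-empty list of normalized [tds_task()] records.
#' @param descriptors Ordered character vector of descriptor labels; defaults
#'   to the labels present in the tasks, in order of first appearance. All
#'   event descriptors must be included.
#' @param grid Evaluation grid from [time_grid()].
#' @return A `tds_curves` object: `values` is a p x |grid| matrix of
#'   proportions (rows named by descriptor), plus `grid` and `n_tasks`.
#' @examples
#' t1 <- tds_task("a", 0, 1, data.frame(time = c(0, 0.5),
#'                                      descriptor = c("D1", "D2")))
#' t2 <- tds_task("b", 0, 1, data.frame(time = 0, descriptor = "D1"))
#' compute_curves(list(t1, t2), grid = time_grid(5))
#' @export
compute_curves <- function(tasks, descriptors = NULL, grid = time_grid()) {
  if (length(tasks) == 0) stop("no tasks supplied", call. = FALSE)
  grid <- check_grid(grid)
  if (is.null(descriptors)) descriptors <- task_descriptors(tasks)
  if (length(descriptors) == 0) {
    stop("no descriptors found and none supplied", call. = FALSE)
  }
  states <- task_state_matrix(tasks, descriptors, grid)
  curves_from_states(states, descriptors, grid)
}

curves_from_states <- function(states, descriptors, grid) {
  p <- length(descriptors)
  n <- nrow(states)
  values <- matrix(0, nrow = p, ncol = ncol(states),
                   dimnames = list(descriptors, NULL))
  for (j in seq_len(p)) {
    values[j, ] <- colMeans(states == j)
  }
  new_tds_curves(values, grid, n)
}

#' @export
print.tds_curves <- function(x, ...) {
  cat(sprintf("<tds_curves> %d descriptor(s) x %d time point(s), n_tasks = %s\n",
              nrow(x$values), length(x$grid), format(x$n_tasks)))
  idx <- unique(round(seq(1, length(x$grid), length.out = min(6, length(x$grid)))))
  m <- round(x$values[, idx, drop = FALSE], 3)
  colnames(m) <- format(round(x$grid[idx], 3))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.tds_curves <- function(x, ...) {
  data.frame(
    t_prime = rep(x$grid, each = nrow(x$values)),
    descriptor = rep(rownames(x$values), times = length(x$grid)),
    proportion = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

#' Plot TDS curves
#'
#' One line per descriptor over normalized time, optionally with an
#' uncertainty band overlaid as shaded polygons.
#'
#' @param x A `tds_curves` object.
#' @param bands Optional `tds_bands` object to shade behind the curves.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tds_curves <- function(x, bands = NULL, ...) {
  p <- nrow(x$values)
  cols <- grDevices::hcl.colors(max(p, 2), "Dark 3")[seq_len(p)]
  graphics::matplot(x$grid, t(x$values), type = "n", ylim = c(0, 1),
                    xlab = "normalized time t'", ylab = "dominance proportion",
                    ...)
  if (!is.null(bands)) {
    stopifnot(inherits(bands, "tds_bands"))
    shade <- grDevices::adjustcolor(cols, alpha.f = 0.2)
    for (j in seq_len(p)) {
      graphics::polygon(c(bands$grid, rev(bands$grid)),
                        c(bands$lower[j, ], rev(bands$upper[j, ])),
                        col = shade[j], border = NA)
    }
  }
  graphics::matlines(x$grid, t(x$values), lty = 1, col = cols)
  graphics::legend("topright", legend = rownames(x$values), col = cols,
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write / read TDS curves as wide CSV
#'
#' The file carries one metadata header line (`# n_tasks: <n>`) followed by a
#' wide table: `t_prime`, then one column per descriptor.
#'
#' @param curves A `tds_curves` object.
#' @param path File path.
#' @return `read_curves` returns a `tds_curves`; `write_curves` returns
#'   `path` invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "tds_curves"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_tasks: %s", format(curves$n_tasks, digits = 17)), con)
  df <- data.frame(t_prime = curves$grid, t(curves$values),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  n_tasks <- NA_real_
  hit <- grep("n_tasks:", meta, value = TRUE)
  if (length(hit) > 0) {
    n_tasks <- as.numeric(sub(".*n_tasks:\\s*", "", hit[1]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  if (names(df)[1] != "t_prime") {
    stop("curve CSV must start with a t_prime column", call. = FALSE)
  }
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  new_tds_curves(values, df$t_prime, n_tasks)
}
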