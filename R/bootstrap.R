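#' Resample TDS tasks with replacement
#'
#' Draws `m` tasks uniformly with replacement from a set of `m` tasks — the
#' bootstrap resampling unit is the whole task, never individual time
#' points, which is what distinguishes this scheme from block bootstraps for
#' time series. Some tasks in the result may coincide.
#'
#' @param tasks Non-empty list of [tds_task()] records.
#' @return A list of `length(tasks)` records drawn with replacement.
#' @export
resample_tasks <- function(tasks) {
  m <- length(tasks)
  if (m == 0) stop("cannot resample an empty task set", call. = FALSE)
  tasks[sample.int(m, m, replace = TRUE)]
}

#' Bootstrap ensemble of TDS curve sets
#'
#' From the observed tasks (sample set P0 with curves C0), draws `q`
#' bootstrap resamples P1..Pq and computes the curve set of each, giving an
#' ensemble C1..Cq whose pointwise spread estimates the uncertainty of C0.
#'
#' Internally the resamples are generated as multinomial task counts
#' (`rmultinom(q, m, uniform)`) and the replicate curves are obtained by a
#' single weighted cross-product against the per-task indicator matrix;
#' this is distribution-identical to materialising each resampled task list
#' and re-running [compute_curves()], but orders of magnitude faster.
#'
#' @param tasks Non-empty list of normalized [tds_task()] records (P0).
#' @param descriptors Ordered descriptor labels (default: those present).
#' @param grid Evaluation grid from [time_grid()].
#' @param q Number of bootstrap replicates (the reference experiments use
#'   1000).
#' @return A `tds_bootstrap` object: `base_curves` (a `tds_curves`, C0),
#'   `replicates` (a `q x p x |grid|` array of curve values), `q`, `m`.
#' @examples
#' pop <- simulate_population(builtin_model(1), 100, seed = 1)
#' ens <- bootstrap_curves(pop, builtin_model(1)$descriptors,
#'                         time_grid(21), q = 200)
#' band_from_order_statistics(ens, "ci95")
#' @export
bootstrap_curves <- function(tasks, descriptors = NULL, grid = time_grid(),
                             q = 1000) {
  if (length(tasks) == 0) stop("no tasks supplied", call. = FALSE)
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  grid <- check_grid(grid)
  if (is.null(descriptors)) descriptors <- task_descriptors(tasks)
  m <- length(tasks)
  p <- length(descriptors)
  states <- task_state_matrix(tasks, descriptors, grid)
  B <- state_onehot(states, p)            # m x (p * G), descriptor fastest
  base <- curves_from_states(states, descriptors, grid)
  W <- stats::rmultinom(q, m, rep(1 / m, m))       # m x q resample counts
  flat <- crossprod(W, B) / m                      # q x (p * G)
  new_tds_bootstrap(base, flat, descriptors, grid, q, m)
}

new_tds_bootstrap <- function(base_curves, flat, descriptors, grid, q, m) {
  structure(
    list(
      base_curves = base_curves,
      replicates = array(flat, dim = c(q, length(descriptors), length(grid)),
                         dimnames = list(NULL, descriptors, NULL)),
      descriptors = descriptors,
      grid = grid,
      q = as.integer(q),
      m = as.integer(m)
    ),
    class = "tds_bootstrap"
  )
}

#' @export
print.tds_bootstrap <- function(x, ...) {
  cat(sprintf("<tds_bootstrap> q = %d replicates of %d descriptor(s) x %d time point(s), m = %d tasks\n",
              x$q, length(x$descriptors), length(x$grid), x$m))
  invisible(x)
}

band_rank <- function(level, q) {
  alpha <- switch(level, ci95 = 0.025, se = 0.1587)
  k <- round(alpha * q)
  if (k < 1) {
    stop("q = ", q, " is too small for the ", toupper(level),
         " band (rank round(", alpha, " * q) < 1); increase q",
         call. = FALSE)
  }
  as.integer(k)
}

new_tds_bands <- function(descriptors, grid, lower, upper, level, method,
                          m = NA_integer_, q = NA_integer_, flags = NULL,
                          clipped = NULL) {
  dimnames(lower) <- dimnames(upper) <- list(descriptors, NULL)
  structure(
    list(descriptors = descriptors, grid = grid, lower = lower,
         upper = upper, level = level, method = method, m = m, q = q,
         flags = flags, clipped = clipped),
    class = "tds_bands"
  )
}

#' @export
print.tds_bands <- function(x, ...) {
  cat(sprintf("<tds_bands> %s %s band, %d descriptor(s) x %d time point(s) (m = %s%s)\n",
              x$method, toupper(x$level), nrow(x$lower), length(x$grid),
              format(x$m), if (is.na(x$q)) "" else paste0(", q = ", x$q)))
  invisible(x)
}

#' Order-statistic uncertainty bands from a bootstrap ensemble
#'
#' At each descriptor and time point the band runs from the k-th smallest to
#' the k-th largest of the `q` replicate curve values: for `q = 1000`,
#' `k = 25` for the 95% confidence interval and `k = 159` for the
#' standard-error band (a central ~68.3% percentile interval, the percentile
#' analogue of one standard error). For other `q` the ranks scale as
#' `k = round(alpha * q)` with `alpha = 0.025` (CI95) or `0.1587 = 1 -
#' pnorm(1)` (SE); if that rank falls below 1 the ensemble is too small and
#' an error asks for a larger `q`. Ties among replicate values are kept as
#' they are (ranks index the sorted multiset; no interpolation).
#'
#' @param ensemble A `tds_bootstrap` from [bootstrap_curves()].
#' @param band `"ci95"` or `"se"`.
#' @return A `tds_bands` object with `lower`/`upper` `p x |grid|` matrices.
#' @export
band_from_order_statistics <- function(ensemble, band = c("ci95", "se")) {
  stopifnot(inherits(ensemble, "tds_bootstrap"))
  band <- match.arg(band)
  q <- ensemble$q
  k <- band_rank(band, q)
  p <- length(ensemble$descriptors)
  G <- length(ensemble$grid)
  flat <- matrix(ensemble$replicates, nrow = q)   # q x (p * G)
  sorted <- apply(flat, 2, sort)
  lower <- matrix(sorted[k, ], nrow = p)
  upper <- matrix(sorted[q + 1L - k, ], nrow = p)
  new_tds_bands(ensemble$descriptors, ensemble$grid, lower, upper,
                band, "bootstrap", m = ensemble$m, q = q)
}

#' Normal-approximation uncertainty bands for TDS curves
#'
#' Dominance proportions are sample proportions, so their uncertainty can be
#' approximated by a normal distribution:
#' \deqn{d_i(t') \pm z \sqrt{d_i(t')(1 - d_i(t'))/m},}
#' with `z = 1.96` for the 95% confidence interval and `z = 1` for the
#' standard error. Bands are clipped to `[0, 1]`; points where the
#' approximation is conventionally unreliable (`m d < 5` or
#' `m (1 - d) < 5`) are flagged in `flags`, and clipping is recorded in
#' `clipped`.
#'
#' @param curves A `tds_curves` object (the sample curves).
#' @param m Sample size (number of tasks behind `curves`); defaults to
#'   `curves$n_tasks`.
#' @param band `"ci95"` or `"se"`.
#' @return A `tds_bands` object.
#' @examples
#' t1 <- tds_task("a", 0, 1, data.frame(time = 0, descriptor = "D1"))
#' cv <- compute_curves(rep(list(t1), 10), c("D1", "D2"), time_grid(5))
#' normal_bands(cv, band = "se")
#' @export
normal_bands <- function(curves, m = curves$n_tasks, band = c("ci95", "se")) {
  stopifnot(inherits(curves, "tds_curves"))
  band <- match.arg(band)
  if (!is.finite(m) || m < 1) stop("m must be a finite count >= 1", call. = FALSE)
  z <- switch(band, ci95 = 1.96, se = 1)
  d <- curves$values
  half <- z * sqrt(d * (1 - d) / m)
  lower <- d - half
  upper <- d + half
  clipped <- lower < 0 | upper > 1
  lower <- pmax(lower, 0)
  upper <- pmin(upper, 1)
  flags <- m * d < 5 | m * (1 - d) < 5
  new_tds_bands(rownames(d), curves$grid, lower, upper, band, "normal",
                m = as.integer(m), flags = flags, clipped = clipped)
}

#' Write uncertainty bands as CSV
#'
#' Metadata header lines (`# method`, `# level`, `# m`, `# q`, `# seed`)
#' followed by a wide table: `t_prime`, then `<descriptor>_lower` and
#' `<descriptor>_upper` columns.
#'
#' @param bands A `tds_bands` object.
#' @param path File path.
#' @param seed Optional seed to record in the metadata.
#' @export
write_bands <- function(bands, path, seed = NA) {
  stopifnot(inherits(bands, "tds_bands"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# method: %s", bands$method),
    sprintf("# level: %s", bands$level),
    sprintf("# m: %s", format(bands$m)),
    sprintf("# q: %s", format(bands$q)),
    sprintf("# seed: %s", format(seed))
  ), con)
  df <- data.frame(t_prime = bands$grid, check.names = FALSE)
  for (j in seq_along(bands$descriptors)) {
    df[[paste0(bands$descriptors[j], "_lower")]] <- bands$lower[j, ]
    df[[paste0(bands$descriptors[j], "_upper")]] <- bands$upper[j, ]
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
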