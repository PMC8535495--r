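#' Population reference curves for a coverage study
#'
#' The "population value" against which band coverage is judged: either the
#' curve set of a finite simulated population of `n` tasks (the reference
#' experiments use `n = 10000`), or, in infinite-population mode, the exact
#' marginal distribution of the model.
#'
#' @param model A [markov_tds_model()].
#' @param n Population size (ignored when `exact = TRUE`).
#' @param exact If `TRUE`, return [exact_marginals()] instead of simulating.
#' @param seed Optional integer seed for the simulation.
#' @return A `tds_curves` object on the model's native grid.
#' @export
population_reference <- function(model, n = 10000, exact = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(model, "markov_tds_model"))
  if (exact) return(exact_marginals(model))
  if (!is.null(seed)) set.seed(seed)
  states <- simulate_trajectories(model, n)
  curves_from_states(states, model$descriptors,
                     seq(0, 1, length.out = model$n_steps + 1L))
}

#' Monte Carlo coverage study of TDS uncertainty bands
#'
#' Measures how often estimated uncertainty bands contain the known
#' population dominance proportions. One study, per sample size `m`:
#'
#' 1. simulate a population of `n` tasks from `model` and take its curve set
#'    as the reference (or the exact marginals in infinite-population mode);
#' 2. for each of `outer_reps` Monte Carlo repetitions, draw `m` tasks from
#'    the population *without* replacement, build the requested bands —
#'    bootstrap order-statistic bands from `q` resamples (with replacement),
#'    and/or normal-approximation bands from the sample curves — and record,
#'    at every descriptor and grid point, whether the reference value lies
#'    inside (endpoints included);
#' 3. report the per-point inclusion probabilities (fraction of repetitions
#'    covering the reference) together with the per-point mean band
#'    halfwidths.
#'
#' A well-calibrated 95% confidence band should include the reference about
#' 95% of the time, and the standard-error band about 68.3%; small `m`
#' underestimates both.
#'
#' @param model A [markov_tds_model()].
#' @param sample_sizes Integer vector of sample sizes `m` (each `<= n`). The
#'   default is a single desk-scale size; the reference experiments sweep
#'   `c(15, 30, 50, 75, 100, 150, 200, 250, 300, 350, 400, 450, 500)`.
#' @param n Population size.
#' @param q Bootstrap replicates per repetition.
#' @param outer_reps Monte Carlo repetitions per sample size.
#' @param methods Subset of `c("bootstrap", "normal")`.
#' @param bands Subset of `c("ci95", "se")`.
#' @param exact_reference Use [exact_marginals()] as the reference instead of
#'   a finite population.
#' @param seed Optional integer seed covering the whole study.
#' @param reference_range Length-2 numeric: points whose reference
#'   proportion lies inside this closed interval enter the headline mean
#'   (proportions near 0 or 1 are conventionally regarded as trivial and can
#'   be excluded); per-point values are always retained.
#' @param verbose Emit progress messages.
#' @param out_dir If non-`NULL`, write one per-point CSV per
#'   (m, method, band) into this directory.
#' @return A `tds_inclusion_study` object: `table` (per-point inclusion
#'   probabilities and mean halfwidths), `summary` (headline means over the
#'   eligible points), plus the study settings.
#' @examples
#' \donttest{
#' st <- run_inclusion_study(builtin_model(1), sample_sizes = 100,
#'                           n = 2000, q = 200, outer_reps = 50, seed = 1)
#' st$summary
#' }
#' @export
run_inclusion_study <- function(model,
                                sample_sizes = 500,
                                n = 10000,
                                q = 1000,
                                outer_reps = 200,
                                methods = c("bootstrap", "normal"),
                                bands = c("ci95", "se"),
                                exact_reference = FALSE,
                                seed = NULL,
                                reference_range = c(0.1, 0.9),
                                verbose = interactive(),
                                out_dir = NULL) {
  stopifnot(inherits(model, "markov_tds_model"))
  methods <- match.arg(methods, c("bootstrap", "normal"), several.ok = TRUE)
  bands <- match.arg(bands, c("ci95", "se"), several.ok = TRUE)
  if (outer_reps < 1) stop("outer_reps must be >= 1", call. = FALSE)
  if (any(sample_sizes > n)) {
    stop("every sample size m must be <= the population size n", call. = FALSE)
  }
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  if ("bootstrap" %in% methods) {
    for (b in bands) band_rank(b, q)   # fail fast if q is too small
  }
  if (!is.null(seed)) set.seed(seed)

  p <- length(model$descriptors)
  G <- model$n_steps + 1L
  grid <- seq(0, 1, length.out = G)

  if (verbose) message("simulating population: n = ", n)
  pop_states <- simulate_trajectories(model, n)
  BP <- state_onehot(pop_states, p)                   # n x (p * G)
  ref_flat <- if (exact_reference) {
    as.vector(exact_marginals(model)$values)          # descriptor fastest
  } else {
    colMeans(BP)
  }
  ref_curves <- new_tds_curves(
    matrix(ref_flat, nrow = p, dimnames = list(model$descriptors, NULL)),
    grid, if (exact_reference) Inf else n)

  combos <- expand.grid(method = methods, band = bands,
                        stringsAsFactors = FALSE)
  tab <- list()
  for (m in sample_sizes) {
    if (verbose) message("m = ", m, ": ", outer_reps, " repetitions, q = ", q)
    hits <- halfw <- matrix(0, nrow = nrow(combos), ncol = p * G)
    ks <- if ("bootstrap" %in% methods) vapply(bands, band_rank, 0L, q = q)
    for (r in seq_len(outer_reps)) {
      idx <- sample.int(n, m)                        # without replacement
      Bm <- BP[idx, , drop = FALSE]
      base <- colMeans(Bm)
      sorted <- NULL
      if ("bootstrap" %in% methods) {
        W <- stats::rmultinom(q, m, rep(1 / m, m))   # m x q
        flat <- crossprod(W, Bm) / m                 # q x (p * G)
        sorted <- apply(flat, 2, sort)
      }
      for (ci in seq_len(nrow(combos))) {
        meth <- combos$method[ci]
        bnd <- combos$band[ci]
        if (meth == "bootstrap") {
          k <- ks[[bnd]]
          lo <- sorted[k, ]
          hi <- sorted[q + 1L - k, ]
        } else {
          z <- if (bnd == "ci95") 1.96 else 1
          h <- z * sqrt(base * (1 - base) / m)
          lo <- pmax(base - h, 0)
          hi <- pmin(base + h, 1)
        }
        hits[ci, ] <- hits[ci, ] + (ref_flat >= lo & ref_flat <= hi)
        halfw[ci, ] <- halfw[ci, ] + (hi - lo) / 2
      }
      if (verbose && r %% 50 == 0) message("  rep ", r, "/", outer_reps)
    }
    for (ci in seq_len(nrow(combos))) {
      tab[[length(tab) + 1L]] <- data.frame(
        m = m,
        method = combos$method[ci],
        band = combos$band[ci],
        descriptor = rep(model$descriptors, times = G),
        t_prime = rep(grid, each = p),
        reference = ref_flat,
        inclusion = hits[ci, ] / outer_reps,
        mean_halfwidth = halfw[ci, ] / outer_reps,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL

  res <- structure(
    list(table = tab,
         summary = NULL,
         reference = ref_curves,
         n = n, q = q, outer_reps = outer_reps, seed = seed,
         exact_reference = exact_reference,
         reference_range = reference_range),
    class = "tds_inclusion_study"
  )
  res$summary <- summary(res, reference_range = reference_range)
  if (!is.null(out_dir)) write_study_csvs(res, out_dir)
  res
}

#' @export
print.tds_inclusion_study <- function(x, ...) {
  cat(sprintf("<tds_inclusion_study> n = %d, q = %d, outer_reps = %d%s\n",
              x$n, x$q, x$outer_reps,
              if (x$exact_reference) " (exact reference)" else ""))
  cat(sprintf("headline means over reference in [%g, %g]:\n",
              x$reference_range[1], x$reference_range[2]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Headline inclusion means of a coverage study
#'
#' Averages the per-point inclusion probabilities over all descriptors and
#' grid points whose reference proportion falls in `reference_range`,
#' per (m, method, band).
#'
#' @param object A `tds_inclusion_study`.
#' @param reference_range Closed interval of eligible reference proportions.
#' @param ... Unused.
#' @return A data frame with columns `m`, `method`, `band`,
#'   `mean_inclusion`, `mean_halfwidth`, `n_points`.
#' @export
summary.tds_inclusion_study <- function(object,
                                        reference_range = object$reference_range,
                                        ...) {
  tab <- object$table
  keep <- tab$reference >= reference_range[1] &
    tab$reference <= reference_range[2]
  el <- tab[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(
    split(el, list(el$m, el$method, el$band), drop = TRUE),
    function(g) data.frame(
      m = g$m[1], method = g$method[1], band = g$band[1],
      mean_inclusion = mean(g$inclusion),
      mean_halfwidth = mean(g$mean_halfwidth),
      n_points = nrow(g),
      stringsAsFactors = FALSE
    )))
  out <- out[order(out$m, out$method, out$band), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_study_csvs <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- study$table
  groups <- split(tab, list(tab$m, tab$method, tab$band), drop = TRUE)
  for (g in groups) {
    fn <- sprintf("inclusion_m%d_%s_%s.csv", g$m[1], g$method[1], g$band[1])
    utils::write.csv(g, file.path(out_dir, fn), row.names = FALSE)
  }
  invisible(out_dir)
}
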