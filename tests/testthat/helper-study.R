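# The Case 1 coverage study shared by the coverage, small-sample and
# halfwidth-agreement checks: one population of 10,000 tasks, sample sizes
# 15 and 500, 1000 bootstrap replicates, 200 Monte Carlo repetitions.
# Computed once per test run.
case1_coverage_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_inclusion_study(
        builtin_model(1), sample_sizes = c(15, 500), n = 10000,
        q = 1000, outer_reps = 200, seed = 2021, verbose = FALSE)
    }
    cache
  }
})
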