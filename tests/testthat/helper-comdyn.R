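# Shared fixtures. Simulated experiments are cached per (seed, n_trials)
# within a test run so several test files can reuse the same tables.

.comdyn_cache <- new.env(parent = emptyenv())

cached_experiment <- function(seed = 1, n_trials = 400,
                              params = model_parameters()) {
  key <- paste0("ex_", seed, "_", n_trials, "_",
                paste0(signif(unlist(unclass(params)), 8), collapse = "|"))
  if (is.null(.comdyn_cache[[key]])) {
    .comdyn_cache[[key]] <- run_experiment(params = params, seed = seed,
                                           n_trials = n_trials)
  }
  .comdyn_cache[[key]]
}

# hand-built trial table for tally tests (schema of run_experiment)
toy_experiment <- function() {
  tibble::tibble(
    trial = 1:12,
    coherence = rep(c(0, 0.256), each = 6),
    correct_side = rep(c("left", "right"), 6),
    choice = c("left", "left", "right", "left", "right", "left",
               "left", "right", "left", "right", "left", "right"),
    correct = choice == correct_side,
    decided = TRUE,
    response_time = c(10, 250, 40, 300, 70, 400, 5, 20, 35, 60, 80, 90),
    is_com = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
               FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_reversals = as.integer(c(0, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0)),
    com_excluded = FALSE,
    peak_uncertainty = c(5, 40, 10, 45, 15, 50, 1, 2, 3, 4, 5, 6),
    motor_complete = TRUE,
    seed = 1:12
  )
}
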