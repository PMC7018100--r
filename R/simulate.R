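#' Derive a per-trial sub-seed from a master seed
#'
#' Counter-based scheme: trial `counter` of a run with master seed `m`
#' gets seed \eqn{(m \cdot 48271 + counter) \bmod (2^{31} - 1)} (the
#' classic minimal-standard multiplier; all arithmetic is exact in
#' doubles). Each trial then runs in its own RNG stream, so per-trial
#' results do not depend on execution order.
#'
#' @param master Master seed (integer).
#' @param counter Trial counter(s), 1-based.
#' @return Integer seed(s) in \[1, 2^31 - 2\].
#' @export
trial_seed <- function(master, counter) {
  m <- 2147483647
  as.integer(((master %% m) * 48271 + counter) %% m + 1)
}

#' Simulate one trial of the decision circuit
#'
#' Integrates the full seven-variable stochastic circuit with the
#' forward Euler-Maruyama scheme (step `params$dt`, default 0.5 ms) from
#' stimulus onset (t = 0) to at most `params$t_max`. The event schedule:
#' the stimulus is on for `t_stim` ms; the uncertainty-monitoring
#' population is released (g = 0) at `t_gate` = 600 ms; when a
#' sensorimotor population's rate first reaches `S_th` = 42.5 Hz the
#' decision is recorded, uncertainty integration is shut down
#' (g = `g_post`) and the hand race is released. Integration always
#' runs the full horizon `t_max`, so reversals occurring after the
#' cursor first reaches a choice target are still observed; the first
#' time a hand population reaches `H_target` (motor response complete)
#' and the first time the cursor mapping passes `C_pos` are recorded as
#' events. Trials with no threshold crossing by `t_max` are
#' non-decision trials (`choice` NA).
#'
#' Response time is reported relative to stimulus offset
#' (`decision_time_raw - t_stim`) and is negative when the threshold is
#' crossed before the offset. A change-of-mind is a reversal of
#' dominance (absolute rate difference > 2 Hz) between the two hand
#' populations after the decision; see [classify_change_of_mind()].
#'
#' @param protocol A [stimulus_protocol()].
#' @param params A [model_parameters()] object.
#' @param store_traces If `TRUE`, keep the full per-step time series.
#' @param noise If `FALSE`, integrate the deterministic skeleton
#'   (equivalent to `sigma_noise = 0`); the result is then seed
#'   invariant.
#' @return A `com_trial` list: `choice` (`"left"`, `"right"` or `NA`),
#'   `choice_initial`, `correct`, `decided`, `response_time` (ms from
#'   stimulus offset), `decision_time_raw`, `is_com`, `n_reversals`,
#'   `peak_uncertainty` (Hz), `motor_complete`, `motor_end_time`,
#'   `t_cursor_target` (first time the cursor mapping passes
#'   `C_pos`), `protocol`, and (optionally) `trace`, a tibble with
#'   columns `t, S_L, S_R, H_L, H_R, y_HU, y_HL, y_HR, x`.
#' @examples
#' tr <- simulate_trial(stimulus_protocol(0.512, "right", seed = 1))
#' tr$choice
#' tr$response_time
#' @export
simulate_trial <- function(protocol, params = model_parameters(),
                           store_traces = FALSE, noise = TRUE) {
  stopifnot(inherits(protocol, "com_protocol"))
  validate_params(params)
  res <- withr::with_seed(
    protocol$seed,
    sim_trial_cpp(unclass(params), protocol$coherence,
                  protocol$correct_side == "right",
                  noise && params$sigma_noise > 0, store_traces)
  )
  as_com_trial(res, protocol)
}

side_label <- function(code) c(NA_character_, "left", "right")[code + 1L]

as_com_trial <- function(res, protocol) {
  choice <- side_label(res$choice_final)
  out <- list(
    choice = choice,
    choice_initial = side_label(res$choice_initial),
    correct = if (is.na(choice)) NA else choice == protocol$correct_side,
    decided = res$decided,
    response_time = res$response_time,
    decision_time_raw = res$decision_time_raw,
    is_com = res$is_com,
    n_reversals = res$n_reversals,
    peak_uncertainty = res$peak_uncertainty,
    motor_complete = res$motor_complete,
    motor_end_time = res$motor_end_time,
    t_cursor_target = res$t_cursor_target,
    n_clip = res$n_clip,
    protocol = protocol
  )
  if (!is.null(res$trace)) {
    tr <- res$trace
    colnames(tr) <- c("t", "S_L", "S_R", "H_L", "H_R", "y_HU",
                      "y_HL", "y_HR", "x")
    out$trace <- tibble::as_tibble(as.data.frame(tr))
  }
  if (out$n_clip > 0) {
    warning("gating variable clipped to [0, 1] on ", out$n_clip, " step(s)",
            call. = FALSE)
  }
  structure(out, class = "com_trial")
}

#' @export
print.com_trial <- function(x, ...) {
  cat("<com_trial> coherence", x$protocol$coherence,
      "correct side", x$protocol$correct_side, "\n")
  if (!x$decided) {
    cat("  non-decision trial (no threshold crossing)\n")
  } else {
    cat("  choice", x$choice,
        if (isTRUE(x$correct)) "(correct)" else "(error)",
        "| RT", format(x$response_time), "ms",
        "| CoM", x$is_com, "| peak uncertainty",
        format(round(x$peak_uncertainty, 2)), "Hz\n")
  }
  invisible(x)
}

#' Classify changes-of-mind from a hand-population trace
#'
#' A simulated trial is a change-of-mind when dominance between the two
#' hand populations reverses after the decision. Dominance episodes are
#' maximal intervals where the absolute rate difference
#' \eqn{|y_{HL} - y_{HR}|} exceeds 2 Hz; `n_reversals` counts sign
#' alternations between successive episodes, and `is_com` is
#' `n_reversals >= 1`. Excursions that never exceed 2 Hz are ignored.
#'
#' @param y_HL,y_HR Hand population rate time series (Hz), equal length;
#'   alternatively `y_HL` may be a matrix/data frame with columns
#'   `y_HL` and `y_HR` (e.g. the `trace` of a [simulate_trial()] run
#'   restricted to the post-decision period).
#' @param threshold Dominance threshold in Hz (default 2).
#' @return A list with `is_com` and `n_reversals`.
#' @examples
#' classify_change_of_mind(c(0, 3, 3, 0, 0), c(0, 0, 0, 3, 4))
#' @export
classify_change_of_mind <- function(y_HL, y_HR = NULL, threshold = 2) {
  if (is.null(y_HR)) {
    m <- y_HL
    y_HR <- m[, "y_HR"]
    y_HL <- m[, "y_HL"]
  }
  y_HL <- as.numeric(y_HL)
  y_HR <- as.numeric(y_HR)
  if (length(y_HL) == 0L) stop("empty hand trace", call. = FALSE)
  if (length(y_HL) != length(y_HR)) {
    stop("y_HL and y_HR must have equal length", call. = FALSE)
  }
  delta <- y_HL - y_HR
  sgn <- sign(delta) * (abs(delta) > threshold)
  sgn <- sgn[sgn != 0]
  if (length(sgn) == 0L) {
    return(list(is_com = FALSE, n_reversals = 0L))
  }
  episodes <- rle(sgn)$values
  n_rev <- sum(diff(episodes) != 0)
  list(is_com = n_rev >= 1, n_reversals = as.integer(n_rev))
}

#' Simulate a full experiment over a design of coherence conditions
#'
#' Runs `n_trials` independent trials per coherence level. The correct
#' side is randomized per trial and every trial runs in its own RNG
#' stream derived from the master seed by the counter scheme of
#' [trial_seed()], so the same master seed always reproduces the same
#' table, row for row.
#'
#' @param design Either a numeric vector of coherence levels (each run
#'   for `n_trials` trials) or a data frame with columns `coherence` and
#'   `n_trials`.
#' @param params A [model_parameters()] object.
#' @param seed Master seed (integer).
#' @param n_trials Trials per condition when `design` is a vector.
#' @param noise Passed to [simulate_trial()].
#' @param progress Print a line per condition.
#' @return A `com_experiment` tibble with one row per trial: `trial`,
#'   `coherence`, `correct_side`, `choice`, `choice_initial`, `correct`,
#'   `decided`, `response_time`, `decision_time_raw`, `is_com`,
#'   `n_reversals`, `com_excluded` (more than one reversal; such trials
#'   are flagged and left out of change-of-mind analyses),
#'   `peak_uncertainty`, `motor_complete`, `seed`. Attributes `params`,
#'   `master_seed` and `design` carry the provenance; [glance()] gives
#'   the run-level summary.
#' @examples
#' ex <- run_experiment(c(0, 0.512), n_trials = 5, seed = 42)
#' dplyr::count(ex, coherence, correct)
#' @export
run_experiment <- function(design = c(0, 0.032, 0.064, 0.128, 0.256, 0.512),
                           params = model_parameters(), seed = 1L,
                           n_trials = 6000L, noise = TRUE,
                           progress = FALSE) {
  if (is.numeric(design) && is.null(dim(design))) {
    design <- tibble::tibble(coherence = as.numeric(design),
                             n_trials = as.integer(n_trials))
  }
  stopifnot(is.data.frame(design),
            all(c("coherence", "n_trials") %in% names(design)))
  validate_params(params)
  withr::local_preserve_seed()
  par_c <- unclass(params)
  noise_on <- noise && params$sigma_noise > 0

  # correct sides for the whole run come from one master-seeded draw,
  # indexed by the trial counter; per-trial sub-streams are noise only,
  # so a row is reproduced exactly by simulate_trial() with its seed
  n_total <- sum(pmax(design$n_trials, 0L))
  set.seed(seed)
  all_sides <- sample(c("left", "right"), n_total, replace = TRUE)

  counter <- 0L
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    co <- design$coherence[i]
    nt <- design$n_trials[i]
    if (nt < 1L) {
      rows[[i]] <- NULL
      next
    }
    res <- vector("list", nt)
    sides <- character(nt)
    seeds <- integer(nt)
    for (k in seq_len(nt)) {
      counter <- counter + 1L
      s <- trial_seed(seed, counter)
      seeds[k] <- s
      sides[k] <- all_sides[counter]
      set.seed(s)
      res[[k]] <- sim_trial_cpp(par_c, co, sides[k] == "right",
                                noise_on, FALSE)
    }
    get_n <- function(f) vapply(res, function(r) as.numeric(r[[f]]),
                                numeric(1))
    get_l <- function(f) vapply(res, function(r) as.logical(r[[f]]),
                                logical(1))
    choice <- side_label(as.integer(get_n("choice_final")))
    rows[[i]] <- tibble::tibble(
      coherence = co,
      correct_side = sides,
      choice = choice,
      choice_initial = side_label(as.integer(get_n("choice_initial"))),
      correct = ifelse(is.na(choice), NA, choice == sides),
      decided = get_l("decided"),
      response_time = get_n("response_time"),
      decision_time_raw = get_n("decision_time_raw"),
      is_com = get_l("is_com"),
      n_reversals = as.integer(get_n("n_reversals")),
      peak_uncertainty = get_n("peak_uncertainty"),
      motor_complete = get_l("motor_complete"),
      seed = seeds
    )
    if (progress) {
      message(sprintf("coherence %.3f: %d trials, %.1f%% non-decision",
                      co, nt, 100 * mean(!rows[[i]]$decided)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    trial = dplyr::row_number(),
    com_excluded = .data$n_reversals > 1L,
    .before = 1
  )
  new_com_experiment(out, params = params, master_seed = seed,
                     design = design)
}

new_com_experiment <- function(tbl, params, master_seed, design) {
  structure(
    tibble::as_tibble(tbl),
    params = params,
    master_seed = master_seed,
    design = design,
    package_version = as.character(utils::packageVersion("comdyn")),
    class = c("com_experiment", class(tibble::tibble()))
  )
}

#' Reference integration of a noise-free trial in plain R
#'
#' Scalar forward-Euler integration of the deterministic circuit built
#' directly from the exported drift functions ([synaptic_drift()],
#' [uncertainty_drift()], [hand_drift()], [io_gain()],
#' [stimulus_current()]). Slow, but independent of the compiled
#' simulator: used to cross-check it, including at finer integration
#' steps than the production `dt`.
#'
#' @param protocol A [stimulus_protocol()] (seed unused: noise-free).
#' @param params A [model_parameters()] object; set `dt` here to refine
#'   the step.
#' @param t_end Integration horizon (ms), default `params$t_max`.
#' @return A tibble with columns `t, S_L, S_R, H_L, H_R, y_HU, y_HL,
#'   y_HR` and attributes `decision_time_raw` and `choice_initial`.
#' @export
reference_trial <- function(protocol, params = model_parameters(),
                            t_end = params$t_max) {
  stopifnot(inherits(protocol, "com_protocol"))
  dt <- params$dt
  n <- round(t_end / dt)
  S_L <- S_R <- params$S_init
  y_u <- y_l <- y_r <- 0
  decided <- FALSE
  t_dec <- NA_real_
  choice <- NA_character_
  out <- matrix(NA_real_, n, 8)
  t <- 0
  for (k in seq_len(n)) {
    I <- stimulus_current(protocol$coherence, protocol$correct_side, t,
                          params)
    x_L <- sensorimotor_input(S_L, S_R, I[["I_L"]], y_u, 0, params)
    x_R <- sensorimotor_input(S_R, S_L, I[["I_R"]], y_u, 0, params)
    H_L <- io_gain(x_L, params)
    H_R <- io_gain(x_R, params)
    if (!decided && (H_L >= params$S_th || H_R >= params$S_th)) {
      decided <- TRUE
      t_dec <- t
      choice <- if (H_L >= H_R) "left" else "right"
    }
    g_u <- if (decided) params$g_post else
      if (t < params$t_gate) params$g_pre else params$g_gate
    g_h <- if (decided) 0 else params$g_hand
    out[k, ] <- c(t, S_L, S_R, H_L, H_R, y_u, y_l, y_r)
    dS <- synaptic_drift(S_L, S_R, H_L, H_R, params)
    dy_u <- uncertainty_drift(y_u, H_L, H_R, g_u, params)
    dy <- hand_drift(y_l, y_r, H_L, H_R, g_h, params)
    S_L <- min(1, max(0, S_L + dt * dS[["dS_L"]]))
    S_R <- min(1, max(0, S_R + dt * dS[["dS_R"]]))
    y_u <- y_u + dt * dy_u
    y_l <- y_l + dt * dy[["dy_HL"]]
    y_r <- y_r + dt * dy[["dy_HR"]]
    t <- t + dt
  }
  colnames(out) <- c("t", "S_L", "S_R", "H_L", "H_R", "y_HU", "y_HL", "y_HR")
  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "decision_time_raw") <- t_dec
  attr(res, "choice_initial") <- choice
  res
}
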