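#' Screen geometry of the mouse-tracking task
#'
#' Describes the response display: a 1920 x 1080 px screen (origin at
#' the top-left corner, y increasing downward), a start button at the
#' bottom centre, and two choice targets in the top corners placed
#' symmetrically about the vertical centre line. The response area is
#' the region between the start button and the targets; its lowest 10%
#' (nearest the start button) is the band in which early erratic
#' movements are ignored by the change-of-mind detector.
#'
#' @param width,height Screen size in px.
#' @param target_offset_x Horizontal distance of each target from the
#'   centre line (px).
#' @param target_y Vertical centre of the targets (px).
#' @param start_y Vertical position of the start button (px).
#' @param target_radius Radius within which a trajectory end point
#'   counts as inside a target (px).
#' @return A `com_geometry` list with fields `width`, `height`,
#'   `centre_x`, `target_left`, `target_right` (x/y pairs), `start`
#'   (x/y), `target_radius`, `response_top`, `response_bottom`,
#'   `band_top` (upper edge of the bottom-10% band).
#' @examples
#' screen_geometry()
#' @export
screen_geometry <- function(width = 1920, height = 1080,
                            target_offset_x = 760, target_y = 100,
                            start_y = 1000, target_radius = 120) {
  stopifnot(width > 0, height > 0, target_offset_x > 0,
            target_y < start_y, start_y <= height)
  centre_x <- width / 2
  structure(list(
    width = width, height = height, centre_x = centre_x,
    target_left = c(x = centre_x - target_offset_x, y = target_y),
    target_right = c(x = centre_x + target_offset_x, y = target_y),
    start = c(x = centre_x, y = start_y),
    target_radius = target_radius,
    response_top = target_y,
    response_bottom = start_y,
    band_top = start_y - 0.1 * (start_y - target_y)
  ), class = "com_geometry")
}

check_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("t", "x", "y") %in% names(traj)))
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 samples",
                            call. = FALSE)
  if (any(diff(traj$t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(traj)
}

traj_meta <- function(traj, field, override = NULL) {
  v <- override %||% attr(traj, field) %||% traj[[field]][1]
  if (is.null(v) || is.na(v)) {
    stop("trajectory is missing '", field, "'", call. = FALSE)
  }
  v
}

#' Label changes-of-mind in a cursor trajectory
#'
#' Applies the experimental labelling rule: a trial is a change-of-mind
#' if the trajectory deviates from the implicit vertical centre line
#' toward the unchosen option by more than `threshold` px (in x).
#' Deviations whose crossing of the threshold occurs while the cursor
#' is in the bottom 10% of the response area are attributed to early
#' erratic movement and ignored. Qualifying excursions must alternate
#' sides to count as multiple changes-of-mind (repeated same-side
#' excursions count once); trials with more than one change-of-mind
#' are flagged for exclusion.
#'
#' @param traj A single-trial trajectory: data frame with columns `t`
#'   (ms, strictly increasing), `x`, `y` (px), plus `chosen_side`
#'   either as a column or attribute.
#' @param geom A [screen_geometry()].
#' @param threshold Deviation threshold in px (100).
#' @param chosen_side Optional override, `"left"` or `"right"`.
#' @return A one-row tibble: `is_com`, `n_com`, `excluded_multi_com`.
#' @export
label_change_of_mind <- function(traj, geom = screen_geometry(),
                                 threshold = 100, chosen_side = NULL) {
  check_trajectory(traj)
  chosen <- match.arg(traj_meta(traj, "chosen_side", chosen_side),
                      c("left", "right"))
  target <- if (chosen == "left") geom$target_left else geom$target_right
  end <- c(traj$x[nrow(traj)], traj$y[nrow(traj)])
  if (sqrt(sum((end - target)^2)) > geom$target_radius) {
    stop("trajectory does not end inside the chosen target; cannot label",
         call. = FALSE)
  }
  dev <- traj$x - geom$centre_x
  # side of each sample beyond the threshold: -1 left, +1 right, 0 inside
  side <- ifelse(dev > threshold, 1L, ifelse(dev < -threshold, -1L, 0L))
  unchosen_sign <- if (chosen == "left") 1L else -1L
  runs <- rle(side)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  ep_side <- runs$values[keep]
  ep_start <- starts[keep]
  # an unchosen-side episode is discarded if its threshold crossing
  # happened inside the bottom-10% band
  in_band <- traj$y[ep_start] > geom$band_top
  ok <- ep_side != unchosen_sign | !in_band
  ep_side <- ep_side[ok]
  if (length(ep_side)) {
    ep_side <- rle(ep_side)$values  # alternation rule
  }
  n_com <- sum(ep_side == unchosen_sign)
  tibble::tibble(is_com = n_com >= 1L, n_com = as.integer(n_com),
                 excluded_multi_com = n_com > 1L)
}

#' Response onset and response time from a cursor trajectory
#'
#' Response onset is the start of the first hand movement whose
#' cumulative cursor displacement exceeds `threshold` px, so that small
#' movements (hand tremor) do not set the onset. Movement segments are
#' delimited by near-stationary periods: stretches with speed below
#' `speed_threshold` lasting at least `min_pause` ms. Response time is
#' onset minus stimulus offset and is negative when the movement began
#' before the offset.
#'
#' @param traj Single-trial trajectory with columns `t`, `x`, `y` and
#'   `stimulus_offset` (column or attribute).
#' @param threshold Displacement defining a response movement (100 px).
#' @param speed_threshold Speed below which the hand counts as
#'   stationary (0.05 px/ms).
#' @param min_pause Minimum stationary duration that separates two
#'   movements (50 ms).
#' @param stimulus_offset Optional override (ms).
#' @return A one-row tibble: `response_onset_time` (ms),
#'   `response_time` (ms relative to stimulus offset).
#' @export
response_onset_time <- function(traj, threshold = 100,
                                speed_threshold = 0.05, min_pause = 50,
                                stimulus_offset = NULL) {
  check_trajectory(traj)
  offset <- traj_meta(traj, "stimulus_offset", stimulus_offset)
  dt <- diff(traj$t)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  moving <- (step / dt) >= speed_threshold
  # stationary runs shorter than min_pause do not split a movement
  runs <- rle(moving)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_id <- integer(length(moving))
  cur <- 0L
  for (k in seq_along(runs$values)) {
    idx <- starts[k]:ends[k]
    if (runs$values[k]) {
      if (cur == 0L) cur <- max(seg_id) + 1L
      seg_id[idx] <- cur
    } else {
      dur <- traj$t[ends[k] + 1L] - traj$t[starts[k]]
      if (dur >= min_pause) cur <- 0L else if (cur > 0L) seg_id[idx] <- cur
    }
  }
  for (s in unique(seg_id[seg_id > 0L])) {
    idx <- which(seg_id == s)
    if (sum(step[idx]) > threshold) {
      onset <- traj$t[idx[1]]
      return(tibble::tibble(response_onset_time = onset,
                            response_time = onset - offset))
    }
  }
  stop("no movement exceeding ", threshold, " px found", call. = FALSE)
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

mj_path <- function(from, to, t0, dur) {
  force(from); force(to); force(t0); force(dur)
  function(t) {
    tau <- pmin(pmax((t - t0) / dur, 0), 1)
    s <- min_jerk(tau)
    cbind(x = from[1] + s * (to[1] - from[1]),
          y = from[2] + s * (to[2] - from[2]))
  }
}

eval_piecewise <- function(segments, t) {
  # segments: list of list(fn, t0, t1); constant extrapolation between
  out <- matrix(NA_real_, length(t), 2)
  for (seg in segments) {
    i <- t >= seg$t0 & t <= seg$t1
    if (any(i)) out[i, ] <- seg$fn(t[i])
  }
  last <- segments[[length(segments)]]
  i <- t > last$t1
  if (any(i)) out[i, ] <- last$fn(rep(last$t1, sum(i)))
  for (k in seq_along(t)) {
    if (is.na(out[k, 1])) {
      prev <- Filter(function(s) s$t1 <= t[k], segments)
      out[k, ] <- if (length(prev)) {
        p <- prev[[length(prev)]]
        p$fn(p$t1)
      } else {
        segments[[1]]$fn(segments[[1]]$t0)
      }
    }
  }
  out
}

#' Generate a synthetic cursor trajectory with ground-truth labels
#'
#' Emits a minimum-jerk-style reach emulating the mouse-tracking task:
#' cursor at the start button during the stimulus, sampled at 60 Hz,
#' then at 100 Hz from stimulus offset; movement onset at a
#' configurable time relative to offset. Kinds:
#' \describe{
#'   \item{direct}{straight reach to the chosen target.}
#'   \item{com}{reach toward the opposite target past the labelling
#'     threshold, then to the chosen target (one change-of-mind).}
#'   \item{multi_com}{two alternating opposite-side excursions before
#'     the final reach (excluded as multiple changes-of-mind).}
#'   \item{early_start}{direct reach starting before stimulus offset
#'     (negative response time).}
#'   \item{tremor}{small (< 15 px) jitter around the start button
#'     before a direct reach; must not affect the detected onset.}
#'   \item{com_low}{opposite-side excursion confined to the bottom 10%
#'     of the response area: not a change-of-mind by the labelling
#'     rule.}
#' }
#'
#' @param kind Trajectory kind, see above.
#' @param geom A [screen_geometry()].
#' @param chosen_side `"left"` or `"right"` (final click side).
#' @param onset Movement onset relative to stimulus offset (ms);
#'   default +150, ignored by `early_start` which uses -100.
#' @param excursion Size of the opposite-side excursion beyond the
#'   centre line (px), default 150.
#' @param jitter_sd Gaussian positional jitter s.d. in px (0 =
#'   noise-free).
#' @param stimulus_offset Stimulus offset time (ms after trial start).
#' @param reach_duration Duration of each movement segment (ms).
#' @return A trajectory tibble (`t`, `x`, `y`) with attributes
#'   `chosen_side`, `stimulus_offset`, `kind` and ground-truth fields
#'   `true_is_com`, `true_n_com`, `true_excluded`, `true_onset`.
#' @examples
#' tr <- generate_synthetic_trajectory("com", chosen_side = "left")
#' label_change_of_mind(tr)
#' @export
generate_synthetic_trajectory <- function(kind = c("direct", "com",
                                                   "multi_com",
                                                   "early_start", "tremor",
                                                   "com_low"),
                                          geom = screen_geometry(),
                                          chosen_side = c("left", "right"),
                                          onset = 150, excursion = 150,
                                          jitter_sd = 0,
                                          stimulus_offset = 800,
                                          reach_duration = 450) {
  kind <- match.arg(kind)
  chosen_side <- match.arg(chosen_side)
  start <- geom$start
  target <- if (chosen_side == "left") geom$target_left else
    geom$target_right
  unchosen_dir <- if (chosen_side == "left") 1 else -1
  if (kind == "early_start") onset <- -100
  t_on <- stimulus_offset + onset
  mid_y <- (geom$response_top + geom$response_bottom) / 2

  segs <- list()
  t0 <- t_on
  add <- function(from, to, dur) {
    seg <- list(fn = mj_path(from, to, t0, dur), t0 = t0, t1 = t0 + dur)
    segs[[length(segs) + 1]] <<- seg
    t0 <<- t0 + dur
    to
  }
  pos <- c(start[["x"]], start[["y"]])
  true_n <- 0L
  if (kind %in% c("com", "multi_com")) {
    way <- c(geom$centre_x + unchosen_dir * (excursion + 60), mid_y)
    pos <- add(pos, way, reach_duration)
    true_n <- 1L
    if (kind == "multi_com") {
      back <- c(geom$centre_x - unchosen_dir * (excursion + 60),
                mid_y - 120)
      pos <- add(pos, back, reach_duration)
      way2 <- c(geom$centre_x + unchosen_dir * (excursion + 40),
                mid_y - 240)
      pos <- add(pos, way2, reach_duration)
      true_n <- 2L
    }
  } else if (kind == "com_low") {
    # excursion entirely inside the bottom-10% band
    band_y <- geom$band_top + 0.5 * (geom$response_bottom - geom$band_top)
    way <- c(geom$centre_x + unchosen_dir * (excursion + 60), band_y)
    pos <- add(pos, way, reach_duration)
    pos <- add(pos, c(geom$centre_x, band_y), reach_duration / 2)
  }
  pos <- add(pos, c(target[["x"]], target[["y"]]), reach_duration)
  t_end <- t0 + 80

  # analytic ground-truth onset: the time the minimum-jerk speed of the
  # first movement segment crosses the detector speed threshold
  seg1 <- segs[[1]]
  L1 <- sqrt(sum((seg1$fn(seg1$t1) - seg1$fn(seg1$t0))^2))
  dur1 <- seg1$t1 - seg1$t0
  mj_speed <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  thr <- 0.05  # px/ms, the detector default
  tau_star <- stats::uniroot(function(tau) (L1 / dur1) * mj_speed(tau) - thr,
                             c(1e-9, 0.5))$root
  true_onset <- t_on + tau_star * dur1

  t_pre <- seq(0, stimulus_offset, by = 1000 / 60)
  t_post <- seq(stimulus_offset + 10, t_end, by = 10)
  tt <- c(t_pre, t_post)
  xy <- eval_piecewise(segs, tt)
  if (kind == "tremor") {
    # two short sub-100-px tremor bursts, separated from each other and
    # from the reach by > 50 ms stationary pauses
    for (b0 in c(t_on - 420, t_on - 260)) {
      i <- tt >= b0 & tt <= b0 + 80
      xy[i, 1] <- xy[i, 1] + 10 * sin(2 * pi * (tt[i] - b0) / 80)
    }
  }
  if (jitter_sd > 0) {
    xy <- xy + matrix(stats::rnorm(length(xy), 0, jitter_sd), ncol = 2)
  }
  out <- tibble::tibble(t = tt, x = xy[, 1], y = xy[, 2])
  attr(out, "chosen_side") <- chosen_side
  attr(out, "stimulus_offset") <- stimulus_offset
  attr(out, "kind") <- kind
  attr(out, "true_is_com") <- kind %in% c("com", "multi_com")
  attr(out, "true_n_com") <- true_n
  attr(out, "true_excluded") <- kind == "multi_com"
  attr(out, "true_onset") <- true_onset
  class(out) <- c("com_trajectory", class(out))
  out
}

#' Generate a labelled set of synthetic trajectories
#'
#' Draws `n` trajectories with random kinds, sides and coherences and
#' returns them in long format together with a ground-truth table,
#' for validating the detector.
#'
#' @param n Number of trials.
#' @param seed RNG seed.
#' @param jitter_sd Positional jitter s.d. (px).
#' @param kinds Kinds to draw from, with equal probability.
#' @param geom A [screen_geometry()].
#' @return A list with `trajectories` (long tibble: `trial`, `t`, `x`,
#'   `y`, `chosen_side`, `correct_side`, `coherence`,
#'   `stimulus_offset`) and `truth` (one row per trial: kind and
#'   ground-truth labels).
#' @export
make_trajectory_set <- function(n, seed = 1, jitter_sd = 0,
                                kinds = c("direct", "com", "multi_com",
                                          "early_start", "tremor",
                                          "com_low"),
                                geom = screen_geometry()) {
  withr::local_seed(seed)
  coh_levels <- c(0, 0.032, 0.064, 0.128, 0.256, 0.512)
  purrr::map(seq_len(n), function(i) {
    kind <- sample(kinds, 1)
    side <- sample(c("left", "right"), 1)
    correct <- sample(c("left", "right"), 1)
    co <- sample(coh_levels, 1)
    onset <- stats::runif(1, 60, 320)
    tr <- generate_synthetic_trajectory(kind, geom, side, onset = onset,
                                        jitter_sd = jitter_sd)
    list(
      traj = dplyr::mutate(tibble::as_tibble(tr), trial = i,
                           chosen_side = side, correct_side = correct,
                           coherence = co, stimulus_offset = 800,
                           .before = 1),
      truth = tibble::tibble(
        trial = i, kind = kind, chosen_side = side, correct_side = correct,
        coherence = co,
        true_is_com = attr(tr, "true_is_com"),
        true_n_com = attr(tr, "true_n_com"),
        true_excluded = attr(tr, "true_excluded"),
        true_onset = attr(tr, "true_onset"),
        true_rt = attr(tr, "true_onset") - 800
      )
    )
  }) -> items
  list(
    trajectories = dplyr::bind_rows(purrr::map(items, "traj")),
    truth = dplyr::bind_rows(purrr::map(items, "truth"))
  )
}

#' Label every trial of a long trajectory table
#'
#' Runs [label_change_of_mind()] and [response_onset_time()] on each
#' trial of a long-format trajectory table (as produced by
#' [make_trajectory_set()] or [read_trajectories()]).
#'
#' @param trajectories Long tibble with columns `trial`, `t`, `x`, `y`,
#'   `chosen_side`, `stimulus_offset` and optionally `correct_side`,
#'   `coherence`.
#' @param geom A [screen_geometry()].
#' @return A tibble with one row per trial: labels plus carried-over
#'   metadata.
#' @export
label_trajectories <- function(trajectories, geom = screen_geometry()) {
  stopifnot(is.data.frame(trajectories), "trial" %in% names(trajectories))
  trajectories |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_map(function(d, key) {
      lab <- label_change_of_mind(d, geom,
                                  chosen_side = d$chosen_side[1])
      rt <- response_onset_time(d, stimulus_offset = d$stimulus_offset[1])
      meta <- tibble::tibble(trial = key$trial)
      for (col in c("chosen_side", "correct_side", "coherence")) {
        if (col %in% names(d)) meta[[col]] <- d[[col]][1]
      }
      dplyr::bind_cols(meta, lab, rt)
    }) |>
    dplyr::bind_rows()
}

#' Summaries of labelled behavioural trials
#'
#' Produces the same summary schemas as the simulation analyses so
#' that model output and (synthetic or real) mouse-tracking data are
#' directly comparable: change-of-mind proportion per coherence,
#' accuracy by coherence and CoM, and CoM probability by response-time
#' tertile.
#'
#' @param labels Tibble from [label_trajectories()], requiring columns
#'   `coherence`, `chosen_side`, `correct_side`, `is_com`,
#'   `excluded_multi_com`, `response_time`.
#' @return A list of `com_summary` tibbles: `p_com` (per coherence),
#'   `psychometric` (accuracy by coherence x CoM), `p_com_rt_tertile`.
#' @export
summarize_behaviour <- function(labels) {
  d <- labels |>
    dplyr::mutate(
      correct = .data$chosen_side == .data$correct_side,
      decided = TRUE,
      com_excluded = .data$excluded_multi_com
    )
  list(
    p_com = com_probability_by(d, "coherence"),
    psychometric = psychometric_by_com(d),
    p_com_rt_tertile = com_probability_by(d, "rt_tertile")
  )
}

#' Read and write cursor-trajectory files
#'
#' Long-format delimited files (comma-separated, one header line) with
#' columns `trial`, `t`, `x`, `y`, `stimulus_offset`, `chosen_side`,
#' `correct_side`, `coherence`. The reader validates strictly
#' increasing timestamps within each trial.
#'
#' @param path File path.
#' @return `read_trajectories()` returns the long tibble;
#'   `write_trajectories()` invisibly returns `path`.
#' @export
read_trajectories <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  need <- c("trial", "t", "x", "y", "stimulus_offset", "chosen_side")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- d |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("non-monotone timestamps in trial(s): ",
         paste(bad$trial, collapse = ", "), call. = FALSE)
  }
  d
}

#' @param trajectories Long trajectory tibble.
#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}
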