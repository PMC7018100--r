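#' Reduced two-variable sensorimotor vector field
#'
#' Deterministic drift of the two gating variables with the uncertainty
#' feedback term replaced by a constant current `feedback` (nA) added to
#' both population inputs, the stimulus on at the given coherence, and
#' noise off. This is the subsystem whose bistability structure explains
#' changes-of-mind: with low feedback it is a winner-take-all system
#' with two choice attractors; sufficiently strong feedback collapses
#' them into a single symmetric (indecision) state.
#'
#' The analysis is run at zero coherence. By default the stimulus
#' current is off: the diagram then describes the network in the
#' post-stimulus phase, where the uncertainty feedback transient acts
#' and reversals arise; set `stimulus = TRUE` for the stimulus-on
#' variant.
#'
#' @param S_L,S_R Gating variables in \[0, 1\].
#' @param feedback Constant uncertainty feedback current (nA).
#' @param coherence Motion coherence (0 for the published analysis).
#' @param params A [model_parameters()] object.
#' @param stimulus If `TRUE`, include the stimulus currents at the
#'   given coherence; default `FALSE` (post-offset field).
#' @return Named numeric `c(dS_L, dS_R)` in 1/ms.
#' @export
reduced_vector_field <- function(S_L, S_R, feedback = 0, coherence = 0,
                                 params = model_parameters(),
                                 stimulus = FALSE) {
  base <- if (stimulus) params$J_A_ext * params$mu_0 else 0
  I_L <- base * (1 + coherence)   # favoured side irrelevant at coherence 0;
  I_R <- base * (1 - coherence)   # left taken as favoured by convention
  x_L <- params$J_N_ii * S_L - params$J_N_ij * S_R + params$I_0 + I_L +
    feedback
  x_R <- params$J_N_ii * S_R - params$J_N_ij * S_L + params$I_0 + I_R +
    feedback
  c(dS_L = -S_L / params$tau_S +
      (1 - S_L) * params$gamma * hz_to_per_ms(io_gain(x_L, params)),
    dS_R = -S_R / params$tau_S +
      (1 - S_R) * params$gamma * hz_to_per_ms(io_gain(x_R, params)))
}

field_fun <- function(feedback, coherence, params, stimulus) {
  function(s) reduced_vector_field(s[1], s[2], feedback, coherence, params,
                                   stimulus)
}

fd_jacobian <- function(f, s, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0)
    e[j] <- h
    J[, j] <- (f(s + e) - f(s - e)) / (2 * h)
  }
  J
}

newton_refine <- function(f, s0, tol = 1e-12, max_iter = 60) {
  s <- s0
  for (i in seq_len(max_iter)) {
    fv <- f(s)
    if (max(abs(fv)) < tol) break
    J <- fd_jacobian(f, s)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damped step, kept inside the unit square
    lambda <- 1
    repeat {
      s_new <- pmin(1, pmax(0, s - lambda * step))
      if (max(abs(f(s_new))) < max(abs(fv)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    s <- s_new
  }
  if (max(abs(f(s))) < 1e-10) s else NULL
}

#' Find all fixed points of the reduced sensorimotor system
#'
#' Seeds a damped Newton refinement from every cell of a dense grid
#' where both components of the vector field change sign (nullcline
#' crossings), deduplicates converged roots, and classifies each by the
#' eigenvalues of a central-finite-difference Jacobian: `stable` (both
#' real parts negative), `saddle` (one positive, one negative) or
#' `unstable`.
#'
#' @param feedback Constant uncertainty feedback current (nA), >= 0.
#' @param coherence Motion coherence, default 0.
#' @param params A [model_parameters()] object.
#' @param n_grid Seed-grid resolution per axis (default 200).
#' @return A tibble with one row per fixed point: `S_L`, `S_R`,
#'   `stability`, `lambda1`, `lambda2` (eigenvalue real parts, sorted
#'   decreasing), `residual`.
#' @examples
#' find_fixed_points(0)      # winner-take-all: two stable + one saddle
#' find_fixed_points(0.05)   # single stable state
#' @export
find_fixed_points <- function(feedback, coherence = 0,
                              params = model_parameters(), n_grid = 200,
                              stimulus = FALSE) {
  stopifnot(feedback >= 0)
  f <- field_fun(feedback, coherence, params, stimulus)
  g <- seq(0, 1, length.out = n_grid)
  # vectorized field over the grid
  SL <- matrix(g, n_grid, n_grid)
  SR <- matrix(g, n_grid, n_grid, byrow = TRUE)
  base <- if (stimulus) params$J_A_ext * params$mu_0 else 0
  xL <- params$J_N_ii * SL - params$J_N_ij * SR + params$I_0 +
    base * (1 + coherence) + feedback
  xR <- params$J_N_ii * SR - params$J_N_ij * SL + params$I_0 +
    base * (1 - coherence) + feedback
  FL <- -SL / params$tau_S +
    (1 - SL) * params$gamma * hz_to_per_ms(io_gain(xL, params))
  FR <- -SR / params$tau_S +
    (1 - SR) * params$gamma * hz_to_per_ms(io_gain(xR, params))
  dim(FL) <- dim(FR) <- c(n_grid, n_grid)
  i <- seq_len(n_grid - 1)
  sign_change <- function(M) {
    (M[i, i] * M[i + 1, i] <= 0) | (M[i, i] * M[i, i + 1] <= 0) |
      (M[i, i] * M[i + 1, i + 1] <= 0)
  }
  cells <- which(sign_change(FL) & sign_change(FR), arr.ind = TRUE)
  roots <- list()
  for (r in seq_len(nrow(cells))) {
    s0 <- c(g[cells[r, 1]] + 0.5 / n_grid, g[cells[r, 2]] + 0.5 / n_grid)
    s <- newton_refine(f, s0)
    if (is.null(s)) next
    dup <- FALSE
    for (rt in roots) {
      if (max(abs(rt - s)) < 1e-6) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- s
  }
  if (!length(roots)) {
    return(tibble::tibble(S_L = numeric(), S_R = numeric(),
                          stability = character(), lambda1 = numeric(),
                          lambda2 = numeric(), residual = numeric()))
  }
  rows <- lapply(roots, function(s) {
    J <- fd_jacobian(f, s)
    ev <- eigen(J, only.values = TRUE)$values
    re <- sort(Re(ev), decreasing = TRUE)
    stability <- if (all(re < 0)) "stable"
      else if (re[1] > 0 && re[2] < 0) "saddle"
      else "unstable"
    tibble::tibble(S_L = s[1], S_R = s[2], stability = stability,
                   lambda1 = re[1], lambda2 = re[2],
                   residual = max(abs(f(s))))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$S_L)
  out
}

#' Sweep the uncertainty feedback and assemble the bifurcation diagram
#'
#' Runs [find_fixed_points()] on each grid value of the constant
#' feedback current and links fixed points across consecutive grid
#' values by nearest-neighbour continuation, yielding the branches of
#' the bifurcation diagram of `S_L` against feedback magnitude.
#'
#' @param feedback_grid Ascending numeric grid of feedback currents (nA).
#' @param coherence Motion coherence, default 0.
#' @param params A [model_parameters()] object.
#' @param n_grid Seed-grid resolution passed to [find_fixed_points()].
#' @return A `com_bifurcation` tibble with columns `feedback`, `S_L`,
#'   `S_R`, `stability`, `lambda1`, `lambda2`, `residual`, `branch`.
#'   Attribute `fold_points` holds feedback values where the number of
#'   stable fixed points changes between consecutive grid values.
#' @examples
#' bd <- bifurcation_scan(seq(0, 0.06, by = 0.01), n_grid = 80)
#' attr(bd, "fold_points")
#' @export
bifurcation_scan <- function(feedback_grid, coherence = 0,
                             params = model_parameters(), n_grid = 200,
                             stimulus = FALSE) {
  feedback_grid <- as.numeric(feedback_grid)
  if (length(feedback_grid) == 0L) {
    out <- tibble::tibble(feedback = numeric(), S_L = numeric(),
                          S_R = numeric(), stability = character(),
                          lambda1 = numeric(), lambda2 = numeric(),
                          residual = numeric(), branch = integer())
    attr(out, "fold_points") <- numeric()
    class(out) <- c("com_bifurcation", class(out))
    return(out)
  }
  if (is.unsorted(feedback_grid)) {
    stop("feedback_grid must be sorted ascending", call. = FALSE)
  }
  fps <- lapply(feedback_grid, function(fb)
    dplyr::mutate(find_fixed_points(fb, coherence, params, n_grid, stimulus),
                  feedback = fb, .before = 1))
  # nearest-neighbour branch linking
  next_branch <- 0L
  prev <- NULL
  for (k in seq_along(fps)) {
    cur <- fps[[k]]
    if (!nrow(cur)) { prev <- cur; next }
    br <- integer(nrow(cur))
    if (!is.null(prev) && nrow(prev)) {
      for (j in seq_len(nrow(cur))) {
        dists <- sqrt((prev$S_L - cur$S_L[j])^2 + (prev$S_R - cur$S_R[j])^2)
        jm <- which.min(dists)
        if (dists[jm] < 0.15 && prev$stability[jm] == cur$stability[j]) {
          br[j] <- prev$branch[jm]
        }
      }
    }
    taken <- br[br != 0L]
    for (j in which(br == 0L)) {
      next_branch <- next_branch + 1L
      br[j] <- next_branch
    }
    cur$branch <- br
    fps[[k]] <- cur
    prev <- cur
  }
  out <- dplyr::bind_rows(fps)
  n_stable <- vapply(fps, function(x) sum(x$stability == "stable"),
                     integer(1))
  fold <- feedback_grid[which(diff(n_stable) != 0) + 1L]
  out <- tibble::as_tibble(out)
  attr(out, "fold_points") <- fold
  attr(out, "coherence") <- coherence
  class(out) <- c("com_bifurcation", class(out))
  out
}

#' Count stable fixed points at a feedback value
#'
#' @inheritParams find_fixed_points
#' @return Integer number of stable fixed points.
#' @export
n_stable_states <- function(feedback, coherence = 0,
                            params = model_parameters(), n_grid = 200,
                            stimulus = FALSE) {
  sum(find_fixed_points(feedback, coherence, params, n_grid,
                        stimulus)$stability == "stable")
}

#' Locate the saddle-node collapse of the winner-take-all regime
#'
#' Bisects the constant feedback current for the value at which the two
#' stable choice attractors of the zero-coherence sensorimotor system
#' merge with the saddle, leaving a single stable steady state: the
#' saddle-node (fold) bifurcation that transiently abolishes the
#' categorical decision when uncertainty feedback is strong.
#'
#' @param params A [model_parameters()] object.
#' @param lower,upper Bracketing feedback values (nA); the stable-state
#'   count must differ between them.
#' @param tolerance Bisection tolerance on the feedback value (nA).
#' @param coherence Motion coherence, default 0.
#' @param n_grid Seed-grid resolution passed to [find_fixed_points()].
#' @return The critical feedback magnitude (nA): smallest value at which
#'   only one stable steady state remains, to within `tolerance`.
#' @examples
#' locate_saddle_node(tolerance = 1e-3, n_grid = 100)
#' @export
locate_saddle_node <- function(params = model_parameters(), lower = 0,
                               upper = 0.06, tolerance = 1e-4,
                               coherence = 0, n_grid = 200,
                               stimulus = FALSE) {
  stopifnot(tolerance > 0, lower < upper)
  n_lo <- n_stable_states(lower, coherence, params, n_grid, stimulus)
  n_hi <- n_stable_states(upper, coherence, params, n_grid, stimulus)
  if (n_lo <= 1 || n_hi != 1) {
    stop("bracket must straddle the collapse: multiple stable states at ",
         "`lower` (found ", n_lo, ") and exactly one at `upper` (found ",
         n_hi, ")", call. = FALSE)
  }
  while (upper - lower > tolerance) {
    mid <- (lower + upper) / 2
    if (n_stable_states(mid, coherence, params, n_grid, stimulus) > 1) {
      lower <- mid
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}
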