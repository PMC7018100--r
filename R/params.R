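#' Model parameters for the uncertainty-monitoring decision circuit
#'
#' Constructs the full parameter set of the reduced decision circuit:
#' two mutually inhibiting sensorimotor populations described by NMDA
#' synaptic gating variables, a single uncertainty-monitoring population
#' that feeds excitation back to both, and two mutually inhibiting hand
#' (motor) populations that produce the cursor response. Defaults are
#' the published single parameter set used for all model results;
#' quantities the original description leaves open (noise amplitude and
#' kinetics, gating constant \eqn{\gamma}, maximum trial duration,
#' initial gating value) are housed here with documented defaults.
#'
#' Unit conventions: rates in Hz, currents in nA, time in ms. The
#' \eqn{\gamma H} products in the gating equations convert Hz to
#' events/ms (see [hz_to_per_ms()]), so every drift is per millisecond.
#'
#' The top-down inhibition `g` of the uncertainty-monitoring population
#' takes three values over a trial: `g_pre` before the gate opens at
#' `t_gate`, `g_gate` during the integration window, and `g_post` after
#' the decision. `g_pre` and `g_post` are large enough to silence the
#' population entirely; `g_gate` is an intermediate inhibition that
#' balances the summed sensorimotor drive, so the uncertainty activity
#' grows only while the choice competition is strong, decays once the
#' stimulus is gone and the competition has collapsed, and thereby
#' produces both the phasic uncertainty transient and a small fraction
#' of non-decision trials. `g_gate` and `sigma_noise` are the two
#' calibrated quantities of the model; see the package vignette for the
#' calibration and its rationale.
#'
#' @param ... Named overrides of any default, e.g. `sigma_noise = 0.01`.
#'
#' @return An object of class `com_params`: a named list with fields
#' \describe{
#'   \item{tau_S, tau_h, tau_mc}{time constants (ms) of the sensorimotor
#'     gating variables, hand populations and uncertainty population
#'     (100, 50, 150).}
#'   \item{a, b, d}{input-output function parameters: gain 270 (V nC)^-1,
#'     rate offset 108 Hz, curvature 0.154 s.}
#'   \item{I_0}{tonic background current, 0.3255 nA.}
#'   \item{J_N_ii, J_N_ij}{recurrent self-excitation 0.248 nA and
#'     cross-inhibition 0.0497 nA between sensorimotor populations.}
#'   \item{mu_0, J_A_ext}{stimulus strength 30 Hz and external coupling
#'     0.00052 nA/Hz; together they set the stimulus current.}
#'   \item{J_mc0}{uncertainty feedback coupling (nA/Hz), 0.002.}
#'   \item{J_VHU}{coupling from sensorimotor rates onto the uncertainty
#'     population, 10 nA.}
#'   \item{J_N_LR, J_N_RL}{mutual inhibition between hand populations,
#'     1 nA each.}
#'   \item{S_th}{sensorimotor decision threshold, 42.5 Hz.}
#'   \item{H_th}{hand rate difference mapped to the choice target,
#'     17.4 Hz (cursor mapping scale, see [map_hand_to_x()]).}
#'   \item{H_target}{hand rate at which the motor response completes,
#'     42.5 Hz.}
#'   \item{G_S}{gain of the sensorimotor input-output function, 1.12.}
#'   \item{gamma}{gating kinetic constant, 0.641 (dimensionless).}
#'   \item{sigma_noise, tau_noise}{Ornstein-Uhlenbeck noise current
#'     stationary s.d. (nA) and time constant (ms); defaults 0.006
#'     and 2.}
#'   \item{tau_r}{time constant (ms) of an optional exponential filter
#'     on the population-rate readout used for threshold detection and
#'     downstream (uncertainty, hand) input; values `<= dt` (the
#'     default) mean the instantaneous rate is used.}
#'   \item{g_pre, g_gate, g_post, g_hand}{top-down inhibition (nA) of
#'     the uncertainty population before the gate opens (1000), during
#'     the integration window from `t_gate` to the decision (218, see
#'     Details), and after the decision (3000); and of the hand
#'     populations before the decision (1000).}
#'   \item{C_pos}{x position of the choice target, 760 px.}
#'   \item{dt}{Euler-Maruyama integration step, 0.5 ms.}
#'   \item{t_gate, t_stim, t_max}{uncertainty gate-opening latency
#'     (600 ms after stimulus onset), stimulus duration (800 ms) and
#'     maximum trial duration (1200 ms).}
#'   \item{S_init}{initial value of both gating variables at stimulus
#'     onset, 0.1.}
#' }
#' @examples
#' p <- model_parameters()
#' p$S_th
#' model_parameters(sigma_noise = 0)$sigma_noise
#' @export
model_parameters <- function(...) {
  p <- list(
    tau_S = 100, tau_h = 50, tau_mc = 150,
    a = 270, b = 108, d = 0.154,
    I_0 = 0.3255,
    J_N_ii = 0.248, J_N_ij = 0.0497,
    mu_0 = 30, J_A_ext = 0.00052,
    J_mc0 = 0.002, J_VHU = 10,
    J_N_LR = 1, J_N_RL = 1,
    S_th = 42.5, H_th = 17.4, H_target = 42.5,
    G_S = 1.12,
    gamma = 0.641,
    sigma_noise = 0.006, tau_noise = 2, tau_r = 0.5,
    g_pre = 1000, g_post = 3000, g_gate = 218, g_hand = 1000,
    C_pos = 760,
    dt = 0.5,
    t_gate = 600, t_stim = 800, t_max = 1200,
    S_init = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "com_params")
}

validate_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    v
  }
  for (nm in names(p)) num1(nm)
  pos <- c("tau_S", "tau_h", "tau_mc", "tau_noise", "dt",
           "t_gate", "t_stim", "t_max", "S_th", "H_th", "H_target")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0", call. = FALSE)
  }
  if (p$dt > p$tau_noise) stop("dt must not exceed tau_noise", call. = FALSE)
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (p$sigma_noise < 0) stop("sigma_noise must be >= 0", call. = FALSE)
  if (p$S_init < 0 || p$S_init > 1) stop("S_init must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.com_params <- function(x, ...) {
  cat("<com_params> reduced decision-circuit parameters\n")
  nm <- names(x)
  val <- vapply(x, function(v) format(v, trim = TRUE), character(1))
  cat(paste0("  ", format(nm), " = ", val), sep = "\n")
  invisible(x)
}

#' Stimulus protocol for a single simulated trial
#'
#' Describes one random-dot-motion trial: the motion coherence (fraction
#' of coherently moving dots, task difficulty), the rewarded side, and
#' the RNG seed of the trial's private noise stream. Stimulus onset
#' defines t = 0; the stimulus lasts `t_stim` ms (fixed-duration
#' viewing, response after offset).
#'
#' @param coherence Motion coherence in \[0, 1\]. The study's levels are
#'   0, 0.032, 0.064, 0.128, 0.256 and 0.512; arbitrary fractions are
#'   accepted.
#' @param correct_side `"left"` or `"right"`.
#' @param seed Integer seed for the trial's noise stream.
#' @return A `com_protocol` list with fields `coherence`, `correct_side`,
#'   `seed`.
#' @examples
#' stimulus_protocol(0.128, "right", seed = 7)
#' @export
stimulus_protocol <- function(coherence, correct_side = c("left", "right"),
                              seed = 1L) {
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      !is.finite(coherence) || coherence < 0 || coherence > 1) {
    stop("coherence must be a single number in [0, 1]", call. = FALSE)
  }
  correct_side <- match.arg(correct_side)
  structure(
    list(coherence = coherence, correct_side = correct_side,
         seed = as.integer(seed)),
    class = "com_protocol"
  )
}

#' Read and write model configuration files
#'
#' A configuration file is a YAML mapping whose keys are parameter names
#' accepted by [model_parameters()]. Missing keys take the packaged
#' defaults; unknown keys are an error (naming the offending keys), so
#' typos cannot silently fall back to defaults. An empty file therefore
#' reproduces the published parameter set exactly.
#'
#' @param path File path of a YAML configuration.
#' @return `load_config()` returns a `com_params` object;
#'   `write_config()` invisibly returns `path`.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' write_config(model_parameters(dt = 0.25), cfg)
#' load_config(cfg)$dt
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  do.call(model_parameters, raw)
}

#' @param params A `com_params` object to serialize.
#' @rdname load_config
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "com_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
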