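#' Threshold-linear input-output function
#'
#' The rectification \eqn{[u]_+ = \max(u, 0)} used by the uncertainty
#' and hand population equations.
#'
#' @param u Numeric vector of net inputs.
#' @return `pmax(u, 0)`.
#' @examples
#' threshold_linear(c(-5, 0, 3))
#' @export
threshold_linear <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop("u must be finite numeric", call. = FALSE)
  }
  pmax(u, 0)
}

#' Convert a firing rate in Hz to events per millisecond
#'
#' Single home of the package's unit bookkeeping: rates are carried in
#' Hz, currents in nA and time in ms, so wherever a rate multiplies a
#' per-ms drift (the \eqn{\gamma H} gating terms) it is divided by 1000.
#'
#' @param rate_hz Firing rate in Hz.
#' @return Rate in events/ms.
#' @export
hz_to_per_ms <- function(rate_hz) rate_hz / 1000

#' Sensorimotor input-output (f-I curve) function
#'
#' Firing rate of a sensorimotor population as a function of its total
#' synaptic current \eqn{x} (nA):
#' \deqn{H(x) = G_S \frac{a x - b}{1 - e^{-d (a x - b)}}.}
#' The function is continuous, nonnegative and strictly increasing; the
#' removable singularity at \eqn{a x = b} equals \eqn{G_S / d} and is
#' evaluated by a series expansion near the singular point. Large
#' arguments use the asymptotic linear branch so the exponential cannot
#' overflow.
#'
#' @param x Total synaptic current (nA), vectorized.
#' @param params A [model_parameters()] object.
#' @return Firing rate(s) in Hz.
#' @examples
#' p <- model_parameters()
#' io_gain(p$b / p$a, p)    # removable singularity: G_S / d
#' io_gain(1.0, p)
#' @export
io_gain <- function(x, params = model_parameters()) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("x must be finite numeric", call. = FALSE)
  }
  z <- params$a * x - params$b
  dz <- params$d * z
  out <- numeric(length(z))
  # |d z| small: H = G_S/d * dz/(1-exp(-dz)); expand t/(1-e^-t) = 1 + t/2 + t^2/12 - t^4/720
  small <- abs(dz) < 1e-4
  if (any(small)) {
    t <- dz[small]
    out[small] <- (params$G_S / params$d) * (1 + t / 2 + t^2 / 12 - t^4 / 720)
  }
  big <- !small & dz > 500
  if (any(big)) out[big] <- params$G_S * z[big]
  rest <- !small & !big
  if (any(rest)) {
    out[rest] <- params$G_S * z[rest] / (1 - exp(-dz[rest]))
  }
  out
}

#' Stimulus currents to the two sensorimotor populations
#'
#' While the stimulus is on (\eqn{0 \le t < t_{stim}}), the population
#' favoured by the motion direction receives
#' \eqn{J_{A,ext}\,\mu_0 (1 + \epsilon/100)} and the other
#' \eqn{J_{A,ext}\,\mu_0 (1 - \epsilon/100)}, with \eqn{\epsilon} the
#' coherence in percent. Outside the stimulus window both currents are
#' zero.
#'
#' @param coherence Motion coherence, fraction in \[0, 1\].
#' @param side Favoured side, `"left"` or `"right"`.
#' @param t Time since stimulus onset (ms).
#' @param params A [model_parameters()] object.
#' @return Named numeric `c(I_L, I_R)` in nA.
#' @examples
#' stimulus_current(0.512, "right", t = 100)
#' stimulus_current(0.512, "right", t = 900)  # stimulus off
#' @export
stimulus_current <- function(coherence, side = c("left", "right"), t,
                             params = model_parameters()) {
  side <- match.arg(side)
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      !is.finite(coherence) || coherence < 0 || coherence > 1) {
    stop("coherence must be a single number in [0, 1]", call. = FALSE)
  }
  if (t < 0 || t >= params$t_stim) {
    return(c(I_L = 0, I_R = 0))
  }
  base <- params$J_A_ext * params$mu_0
  hi <- base * (1 + coherence)
  lo <- base * (1 - coherence)
  if (side == "left") c(I_L = hi, I_R = lo) else c(I_L = lo, I_R = hi)
}

#' Total synaptic current into one sensorimotor population
#'
#' \deqn{x_i = J_{N,ii} S_i - J_{N,ij} S_j + I_0 + I_i + J_{mc0}\,y_{HU}
#'       + I_{\eta,i},}
#' i.e. recurrent self-excitation, cross-inhibition from the other
#' population, tonic background, stimulus input, equal excitatory
#' feedback from the uncertainty-monitoring population, and the
#' population's Ornstein-Uhlenbeck noise current.
#'
#' @param S_i,S_j Own and opposing gating variables in \[0, 1\].
#' @param I_stim Stimulus current to this population (nA).
#' @param y_HU Uncertainty-population rate (Hz).
#' @param I_eta Noise current (nA), default 0.
#' @param params A [model_parameters()] object.
#' @return Total current in nA.
#' @export
sensorimotor_input <- function(S_i, S_j, I_stim, y_HU, I_eta = 0,
                               params = model_parameters()) {
  params$J_N_ii * S_i - params$J_N_ij * S_j + params$I_0 + I_stim +
    params$J_mc0 * y_HU + I_eta
}

#' Drift of the NMDA synaptic gating variables
#'
#' \deqn{\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\,H_i,}
#' with \eqn{H_i} in events/ms (see [hz_to_per_ms()]). The \eqn{(1-S)}
#' factor makes the drift non-positive at S = 1 and the decay term
#' vanishes at S = 0 when H = 0, so the unit interval is forward
#' invariant.
#'
#' @param S_L,S_R Gating variables in \[0, 1\].
#' @param H_L,H_R Sensorimotor firing rates (Hz), nonnegative.
#' @param params A [model_parameters()] object.
#' @return Named numeric `c(dS_L, dS_R)` in 1/ms.
#' @export
synaptic_drift <- function(S_L, S_R, H_L, H_R, params = model_parameters()) {
  stopifnot(S_L >= 0, S_L <= 1, S_R >= 0, S_R <= 1, H_L >= 0, H_R >= 0)
  c(dS_L = -S_L / params$tau_S +
      (1 - S_L) * params$gamma * hz_to_per_ms(H_L),
    dS_R = -S_R / params$tau_S +
      (1 - S_R) * params$gamma * hz_to_per_ms(H_R))
}

#' Drift of the uncertainty-monitoring population
#'
#' \deqn{\tau_{mc}\frac{dy_{HU}}{dt} =
#'   [J_{VHU}(H_L + H_R) - g]_+ - y_{HU}.}
#' The top-down inhibition `g` implements the gating schedule: `g_pre`
#' (1000 nA) from trial start, 0 from `t_gate` (600 ms after stimulus
#' onset) so the summed sensorimotor input is integrated, and `g_post`
#' (3000 nA) from the moment a sensorimotor population crosses the
#' decision threshold, after which the activity decays back to zero.
#'
#' @param y_HU Current uncertainty-population rate (Hz).
#' @param H_L,H_R Sensorimotor firing rates (Hz).
#' @param g Top-down inhibition (nA).
#' @param params A [model_parameters()] object.
#' @return dy_HU/dt in Hz/ms.
#' @export
uncertainty_drift <- function(y_HU, H_L, H_R, g, params = model_parameters()) {
  stopifnot(y_HU >= 0, H_L >= 0, H_R >= 0)
  (threshold_linear(params$J_VHU * (H_L + H_R) - g) - y_HU) / params$tau_mc
}

#' Drift of the two hand (motor) populations
#'
#' \deqn{\tau_h \frac{dy_{HL}}{dt} = [H_L - J_{N,LR}\,y_{HR} - g]_+ - y_{HL}}
#' and the mirrored equation for the right population. Mutual inhibition
#' makes the pair a line-attractor race once the pre-decision
#' suppression `g = g_hand` is released (`g = 0`) at the decision.
#'
#' @param y_HL,y_HR Hand population rates (Hz), nonnegative.
#' @param H_L,H_R Driving sensorimotor rates (Hz).
#' @param g Top-down inhibition (nA).
#' @param params A [model_parameters()] object.
#' @return Named numeric `c(dy_HL, dy_HR)` in Hz/ms.
#' @export
hand_drift <- function(y_HL, y_HR, H_L, H_R, g, params = model_parameters()) {
  stopifnot(y_HL >= 0, y_HR >= 0, H_L >= 0, H_R >= 0)
  c(dy_HL = (threshold_linear(H_L - params$J_N_LR * y_HR - g) - y_HL) /
      params$tau_h,
    dy_HR = (threshold_linear(H_R - params$J_N_RL * y_HL - g) - y_HR) /
      params$tau_h)
}

#' Ornstein-Uhlenbeck noise current: drift and diffusion
#'
#' Each sensorimotor population receives an independent OU noise current
#' \eqn{dI_\eta = -I_\eta/\tau_{noise}\,dt +
#' \sigma_{noise}\sqrt{2/\tau_{noise}}\,dW}, whose stationary standard
#' deviation is exactly `sigma_noise`. With `sigma_noise = 0` the
#' process decays deterministically to zero (noise-off mode).
#'
#' @param I_eta Current value of the noise current (nA).
#' @param params A [model_parameters()] object.
#' @return Named numeric `c(drift, diffusion)`: drift in nA/ms and the
#'   diffusion coefficient in nA/sqrt(ms).
#' @export
ou_noise_drift <- function(I_eta, params = model_parameters()) {
  c(drift = -I_eta / params$tau_noise,
    diffusion = params$sigma_noise * sqrt(2 / params$tau_noise))
}

#' Map hand population rates onto cursor x position
#'
#' Linear read-out \eqn{x = q\,(y_{HL} - y_{HR})} with
#' \eqn{q = |C_{pos}| / H_{th}}: a rate difference of `H_th` (17.4 Hz)
#' places the cursor on a choice target at `C_pos` (760 px). Sign
#' convention: positive x points toward the Left target.
#'
#' @param y_HL,y_HR Hand population rates (Hz), vectorized.
#' @param params A [model_parameters()] object.
#' @return Cursor x position(s) in px.
#' @examples
#' map_hand_to_x(17.4, 0)   # 760
#' @export
map_hand_to_x <- function(y_HL, y_HR, params = model_parameters()) {
  if (any(y_HL < 0) || any(y_HR < 0)) {
    stop("hand rates must be nonnegative", call. = FALSE)
  }
  (abs(params$C_pos) / params$H_th) * (y_HL - y_HR)
}
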