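---
title: "A reduced circuit model of decision uncertainty and changes-of-mind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced circuit model of decision uncertainty and changes-of-mind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

comdyn simulates perceptual decisions in a fixed-duration
random-dot-motion task with a reduced cortical circuit in which a
dedicated *uncertainty-monitoring* neural population feeds excitation
back into the choice circuit. The feedback transiently destabilises the
winner-take-all attractor that represents the categorical choice and can
reverse an initial decision downstream, in the motor (hand) populations
— a change-of-mind (CoM) arising without any new post-decision sensory
evidence. This vignette is the package's account of the model, its
parameters, the numerical choices, and what the tests do and do not
establish.

## The circuit

Three modules, seven dynamical variables, all integrated with a forward
Euler–Maruyama scheme at `dt = 0.5` ms.

**Sensorimotor module.** Two mutually inhibiting populations selective
for leftward/rightward motion, each summarised by an NMDA synaptic
gating variable $S_i \in [0,1]$ (the reduced two-variable mean-field
description of a spiking decision network):

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma H_i, \qquad
H_i = G_S\,\frac{a x_i - b}{1 - e^{-d\,(a x_i - b)}},$$

$$x_i = J_{N,ii} S_i - J_{N,ij} S_j + I_0 + I_i + J_{mc0}\,y_{HU}
      + I_{\eta,i},$$

with stimulus input $I_i = J_{A,ext}\,\mu_0 (1 \pm c)$ for motion
coherence $c$ during the 800 ms stimulus window and zero outside it.
Rates are carried in Hz, currents in nA and time in ms; the $\gamma H$
product converts Hz to events/ms (`hz_to_per_ms()`), the single place
unit bookkeeping happens.

**Uncertainty-monitoring module.** One population receiving the summed
sensorimotor rates under a time-varying top-down inhibition $g$:

$$\tau_{mc}\,\frac{dy_{HU}}{dt} =
  \left[\,J_{VHU}(H_L + H_R) - g\,\right]_+ - y_{HU}.$$

Its output excites both sensorimotor populations equally
($J_{mc0}\,y_{HU}$ in $x_i$), closing a positive feedback loop that is
strongest when the two populations remain in competition.

**Hand module.** A line-attractor race of two threshold-linear
populations driven by the corresponding sensorimotor rates,

$$\tau_h\,\frac{dy_{HL}}{dt} = [\,H_L - J_{N,LR}\,y_{HR} - g_h\,]_+
  - y_{HL},$$

(and the mirror equation), suppressed ($g_h$ large) until the decision.
Cursor position is the linear read-out $x = q\,(y_{HL} - y_{HR})$ with
$q = |C_{pos}|/H_{th} = 760/17.4$ px/Hz, so a 17.4 Hz rate difference
puts the cursor on a choice target at $\pm 760$ px.

## Event schedule within a trial

* $t = 0$: stimulus onset. $g = g_{pre} = 1000$ nA silences the
  uncertainty population; hand populations suppressed.
* $t = 600$ ms (`t_gate`): the uncertainty gate opens, $g$ drops to
  `g_gate` and the summed sensorimotor input is integrated.
* $t = 800$ ms (`t_stim`): stimulus offset.
* Decision: the first time a sensorimotor rate reaches
  $S_{th} = 42.5$ Hz. The raw crossing time is stored; response time is
  reported relative to stimulus offset (negative if the crossing
  precedes it, as in the experimental convention). At that moment
  $g \to g_{post} = 3000$ nA (uncertainty integration stops and the
  activity decays) and the hand race is released.
* The integration always runs the full horizon `t_max`; reaching the
  cursor target does not stop it, so reversals that occur after the
  cursor first arrives at a target are observed. The first crossing of
  the 42.5 Hz hand target and the first cursor arrival at $\pm C_{pos}$
  are both recorded as events.
* A trial with no sensorimotor crossing by `t_max` is a non-decision
  trial.

A model CoM is a reversal of dominance between the hand populations
after the decision: dominance episodes are maximal intervals with
$|y_{HL} - y_{HR}| > 2$ Hz, and `n_reversals` counts sign alternations
between successive episodes. The 2 Hz criterion is essentially the
experimental 100 px rule mapped through the cursor gain
($100\,\mathrm{px} / q = 2.29$ Hz). Trials with more than one reversal
are flagged (`com_excluded`) and left out of CoM analyses, mirroring
the exclusion of multi-CoM trials in the experimental pipeline.

## Parameters, units, defaults

`model_parameters()` returns the full set; the published single
parameter set is the default (time constants $\tau_S, \tau_h, \tau_{mc}$
= 100, 50, 150 ms; f–I parameters $a, b, d$ = 270 (VnC)$^{-1}$, 108 Hz,
0.154 s; couplings $J_{N,ii}, J_{N,ij}$ = 0.248, 0.0497 nA;
$I_0 = 0.3255$ nA; $\mu_0 = 30$ Hz; $J_{A,ext} = 0.00052$ nA/Hz;
$J_{mc0} = 0.002$; $J_{VHU} = 10$ nA; hand inhibition 1 nA; thresholds
$S_{th} = 42.5$, $H_{th} = 17.4$ Hz; gain $G_S = 1.12$). Four
quantities the source description leaves open are set here and exposed
in the configuration:

* `gamma = 0.641` — the gating kinetic constant of the parent
  two-variable model, from which the sensorimotor equations are taken
  unchanged.
* `sigma_noise = 0.006` nA, `tau_noise = 2` ms — independent
  Ornstein–Uhlenbeck noise currents in each sensorimotor input, the
  stochastic term required by the Euler–Maruyama scheme, parameterised
  so the stationary standard deviation is exactly `sigma_noise`.
* `g_gate = 218` nA — the top-down inhibition of the
  uncertainty-monitoring population *during* the integration window.
  The published schedule names the values before the window (1000 nA)
  and after the decision (3000 nA) but the sentence describing the
  window itself is incomplete. A literal $g = 0$ makes the feedback
  loop run away within ~20 ms of the gate opening (every trial decides
  immediately; non-decisions cannot occur), so an intermediate
  inhibition that approximately balances the summed drive is the only
  reading consistent with the reported behaviour of the model. Under
  it, uncertainty grows while the choice competition is unresolved,
  dies out after stimulus offset once the competition has collapsed,
  and thereby produces both the phasic uncertainty transient and a
  small fraction of non-decision trials.
* `t_max = 1200` ms — the trial horizon (stimulus plus a 400 ms
  response window). Much longer horizons let marginal trials creep over
  threshold seconds late with saturated uncertainty, which is
  inconsistent with the reported tight coupling between uncertainty
  and response time.
* `S_init = 0.1` — both gating variables at stimulus onset (the parent
  model's conventional starting value); noise currents and all rates
  start at zero.

`g_gate` and `sigma_noise` were calibrated once, jointly with `t_max`,
against the reported simulation-level statistics (a non-decision rate
near 3.4% and a strong positive uncertainty–response-time correlation,
with CoM probability peaked at low coherence and vanishing at the
highest coherence) and then frozen; they are recorded in every run
manifest. At this operating point a full 36,000-trial run yields a
non-decision rate of 3.3–3.6% across master seeds and
$r(\text{peak uncertainty}, \text{RT}) \approx 0.85$.

## Numerical choices

* The f–I curve's removable singularity at $a x = b$ is evaluated by a
  series expansion of $t/(1 - e^{-t})$ for $|t| < 10^{-4}$, and the
  linear asymptote is used once the exponent would underflow; the curve
  is continuous and strictly increasing (grid-tested).
* Euler updates clip $S$ into $[0,1]$ and count clips (a warning is
  raised if any occur; none do at the default step). Rates stay
  nonnegative by construction since `dt` is below every time constant.
* Exact ties of the two rates at threshold are broken by a single
  uniform draw (counted); in noise-off symmetric runs this is the only
  stochastic event.
* Per-trial RNG streams derive from the master seed by a counter
  scheme, `trial_seed(master, counter)` (minimal-standard multiplier,
  exact in doubles), and correct sides come from one master-seeded
  draw indexed by the counter. Rows are therefore order-insensitive and
  each is reproduced bit-exactly by `simulate_trial()` with the row's
  recorded sub-seed.
* An optional exponential filter (`tau_r`) on the rate read-out used
  for threshold detection and downstream input is available; at the
  default `tau_r = dt` the instantaneous rate is used and the compiled
  integrator agrees with the plain-R reference integrator
  (`reference_trial()`) to machine precision in noise-off mode.

## Stability analysis

`find_fixed_points()` finds all equilibria of the two-variable
sensorimotor subsystem with the uncertainty feedback replaced by a
constant current: nullcline sign-change cells on a dense grid (default
200×200) seed a damped Newton refinement; roots are deduplicated,
required to satisfy a $10^{-10}$ residual bound, and classified by the
eigenvalues of a central finite-difference Jacobian.
`locate_saddle_node()` bisects the feedback for the smallest magnitude
at which exactly one stable state remains.

The analysis is run at zero coherence with the stimulus off — the
post-offset network is the one in which the feedback transient acts and
reversals arise. In that field the choice attractors coexist with the
low-activity spontaneous state at weak feedback, and the
winner-take-all structure collapses to a single stable state at
0.0326 nA (the stimulus-on variant, exposed via `stimulus = TRUE`,
collapses earlier, near 0.017 nA). During a high-uncertainty trial the
feedback term $J_{mc0} y_{HU}$ sweeps across this critical value, which
is the mechanism behind reversals: the choice state temporarily loses
stability, the populations re-converge, and noise can re-resolve the
competition the other way.

## The synthetic trajectory generator

`generate_synthetic_trajectory()` emulates the mouse-tracking task
display: a 1920×1080 px screen, start button at the bottom centre,
choice targets at $\pm 760$ px in the top corners, cursor sampled at
60 Hz during the stimulus and 100 Hz afterwards, minimum-jerk movement
segments with configurable onset relative to stimulus offset,
excursion amplitude and Gaussian positional jitter. Six kinds cover the
behaviours the labelling rules must separate: `direct`, `com`,
`multi_com`, `early_start` (negative response time), `tremor`
(sub-100-px bursts that must not set the onset) and `com_low` (an
opposite-side excursion confined to the bottom 10% of the response
area, which the rule must ignore). Each trajectory carries its ground
truth; the ground-truth onset is the analytic time the minimum-jerk
speed crosses the detector's speed threshold.

What the generator does *not* emulate: kinematic variability of real
hands (velocity profiles beyond minimum jerk, curvature habits,
participant-specific speed), device quantisation, or any coupling
between trajectory shape and task difficulty. Passing the recovery
tests therefore shows the labelling rules are implemented correctly and
are robust to positional jitter — not that they are optimal for real
mouse data. The speed-based movement segmenter (stationary below
0.05 px/ms sustained ≥ 50 ms; both configurable) assumes approximately
smooth input: under heavy per-sample white jitter the speed signal
saturates and onsets should be extracted after smoothing.

Coordinate convention, stated once: origin top-left, y increasing
downward; the "bottom 10% of the response area" is the band nearest
the start button.

## Analysis conventions

* Peak uncertainty (the trial-level uncertainty measure) is the
  maximum of $y_{HU}$ over the trial, computed as a streaming reduction
  during integration and equal to the trace maximum when traces are
  stored.
* Min–max normalisation to $[0,1]$ is applied to uncertainty before
  tertile splits and group means; constant input is an explicit error.
* Tertiles are empirical 1/3 and 2/3 quantile groups (`dplyr::ntile`)
  over decided, non-excluded trials: response-time tertiles within each
  coherence condition (matching per-coherence panels), uncertainty
  tertiles across the run; both scopes are exposed as options.
* Trials with zero peak uncertainty (decision before the gate opened)
  are excluded from the uncertainty–RT correlation.
* Summary curves report mean, standard error (sample s.d./$\sqrt{n}$)
  and group size; group sizes always sum to the analysed-trial count.

## Known limitations

* The uncertainty–RT correlation saturates near 0.85 at the default
  operating point rather than 0.95: with the leaky integration of the
  uncertainty population, peak uncertainty approaches its input
  asymptote for late decisions, bending the relation at long response
  times. Regimes with a weaker gate (`g_gate` ≈ 150–170 nA) straighten
  it (r ≈ 0.95–0.98) but eliminate non-decision trials entirely and
  inflate the CoM rate tenfold; the default prefers joint plausibility
  over optimising a single statistic.
* Reversals concentrate in, but are not perfectly confined to, the
  longest response-time tertile: the reversal hazard extends over the
  ~300–500 ms of feedback decay after the decision, so occasional
  mid-tertile trials reverse.
* The model's psychometric function is steeper than typical
  experimental ones (accuracy saturates by coherence 0.128), so error
  trials exist only at the three lowest coherences; the
  uncertainty-by-outcome '<' pattern is assessed over the coherences at
  which both outcomes occur.

## Problem sizes

The packaged defaults simulate 6,000 trials per coherence level
(36,000 trials, ~15 s compiled) for experiment-level statistics and
600 per level in quick mode; the bifurcation scan uses a 200×200 seed
grid and $10^{-4}$ nA bisection tolerance. The test suite runs reduced
designs (150–600 trials per condition) for property checks and the full
design for the acceptance-level statistics.

```{r example}
library(comdyn)
ex <- run_experiment(seed = 1, n_trials = 6000)
glance(ex)                      # run-level rates, r(uncertainty, RT)
tidy(ex)                        # per-coherence summaries
autoplot(com_probability_by(ex, "rt_tertile"))
bd <- bifurcation_scan(seq(0, 0.06, by = 0.002))
autoplot(bd)
locate_saddle_node()            # ~0.0326 nA
```
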