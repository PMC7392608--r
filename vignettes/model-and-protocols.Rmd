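---
title: "Dopaminergic prediction errors for planning and habit formation: model and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopaminergic prediction errors for planning and habit formation: model and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(habitsim)
```

habitsim simulates a basal-ganglia architecture in which dopaminergic
prediction errors play a dual role: within a trial they drive the gradient
dynamics that plan an action, and between trials they gate the plasticity
that updates the model's parameters. This vignette lays out the model, the
numerical choices behind the implementation, what the synthetic protocols
emulate, and the limitations a user should know about.

## The generative model and the planning objective

On a trial the agent observes a stimulus of intensity $s$, receives a
reward expectation $v$ from a valuation system, and must choose an action
intensity $a$ (think: how vigorously to press a lever). Two systems encode
complementary knowledge as Gaussian distributions:

* the **goal-directed system** encodes the likelihood of total reward $R$
  given the action, $R \sim \mathcal N(a\,q\,s,\ \Sigma_g)$, with gain $q$
  (reward per unit action $\times$ stimulus);
* the **habit system** encodes a prior over actions in this state,
  $a \sim \mathcal N(h\,s,\ \Sigma_h)$, with habit gain $h$.

The planned action maximises the posterior $P(a \mid R, s)$, equivalently
the log numerator

$$F(a) = -\frac{(R - a q s)^2}{2\Sigma_g} - \frac{(a - h s)^2}{2\Sigma_h}
         - \tfrac12 \ln \Sigma_g - \tfrac12 \ln \Sigma_h ,$$

whose unique maximiser is a precision-weighted compromise between the
action the likelihood implies ($R/qs$) and the habitual action ($hs$):

```{r map}
p <- intensity_params(q = 1, h = 0, sigma_g = 1, sigma_h = 1)
map_action(R = 2, s = 1, p)
```

The $-\tfrac12\ln\Sigma$ terms are retained in `objective_f()` so that one
objective generates every update rule in the package, including the
variance updates; for unit variances they vanish and play no role in
planning.

Planning is implemented as gradient dynamics on $F$ carried by two
prediction-error units,

$$\tau_\delta\,\dot\delta_g = r + v - a q s - \Sigma_g\,\delta_g, \qquad
  \tau_\delta\,\dot\delta_h = a - h s - \delta_h, \qquad
  \tau\,\dot a = \delta_g\,q\,s + \frac{h s - a}{\Sigma_h}.$$

$\delta_g$ relaxes to the precision-weighted reward prediction error
$(R - aqs)/\Sigma_g$ — the dopaminergic teaching signal of the
goal-directed system — and its gain on the striatal drive $q s$ is what
pushes the plan until the expected reward matches the available reward.
$\delta_h$ signals how the current action differs from the habitual one;
it does not need precision weighting because the habit contribution to
$\dot a$ is already divided by $\Sigma_h$. With the drive held fixed, the
dynamics converge to `map_action()`; this closed form is used as an
independent oracle throughout the test suite.

## The valuation system

The valuation system is a continuous-time temporal-difference learner.
Post-stimulus time is tiled into `n_intervals` intervals of length
$I = 0.2$; a one-hot indicator $s_v$ marks the current interval, one
weight $w_j$ per interval estimates the reward still to come, and

$$\tau\,\dot v = w\,s_v - v, \qquad
  \tau_\delta\,\dot\delta_v = r + v - v(t - I) - \delta_v, \qquad
  \tau\,\dot e = \lambda\,e(t - I - 3\tau) + s_v - e, \qquad
  \tau\,\dot r = r_0 - r.$$

$\delta_v$ converges to the difference between the total reward $r + v$
and the value predicted one interval earlier — the classic
temporal-difference error. The smoothed reward signal $r$ rises with the
same time constant with which $v$ decays at the outcome, so a perfectly
predicted reward produces no error. Eligibility traces $e$ are recycled
from one interval to the next with retention $\lambda = 0.9$; the extra
$3\tau$ in the recycling lag skips the relaxation transient at interval
boundaries.

Two numerical choices matter here:

* **Credit assignment.** Weight updates pair $\delta_v$ with the *lagged*
  trace $e(t - I - 3\tau)$:
  $\dot w = \alpha_v\,\delta_v\,e(t - I - 3\tau)$, clamped at zero. This
  is the standard temporal-difference pairing — the error generated at an
  interval transition corrects the prediction formed in the preceding
  interval. Pairing the error with the instantaneous trace instead lets
  the value jump at stimulus onset credit its own interval's weight, a
  positive feedback with no fixed point (the weights diverge); confining
  updates to the reward window instead produces a beat between the
  0.35-long recycling lag and the 0.2-long intervals that concentrates
  credit on alternating intervals. With the lagged pairing the weights
  equalise at the mean obtained reward, giving the flat post-stimulus
  value ramp characteristic of a trained temporal-difference critic.
* **dt-scaling.** All continuous-time updates are multiplied by the Euler
  step, so halving `dt` does not change learning per unit simulated time.

The two-action choice model uses a simplified valuation system with one
weight per discrete state and asymmetric learning rates
($\alpha_v = 0.5$ when the error is positive, $0.1$ otherwise), updated
once per trial.

## Trial structure and learning

A trial spans $t \in [0, 3]$: stimulus onset at $t = 1$, execution and
outcome at $t = 2$. At execution, motor noise of SD $\sigma_a = 1$ is
added to the planned intensity, the environment returns the reward, and
the action variable is held at the executed value for the remainder of
the trial, so that learning evaluates the prediction errors at the action
actually emitted (this is also why the habit error at the outcome carries
the sign of executed-minus-habitual intensity, regardless of the reward).
The reward is presented for one valuation interval
(`reward_duration = 0.2`; the exact presentation length is a free choice
and is exposed in `dynamics_config()`).

Actor parameters update only while the reward is present, by three-factor
rules gated by the dopaminergic errors:

$$\dot q = \alpha_g\,\delta_g\,a\,s, \quad
  \dot h = \alpha_h\,\delta_h\,s, \quad
  \dot\Sigma_g = \alpha_{\Sigma g}(\Sigma_g^2 \delta_g^2 - \Sigma_g), \quad
  \dot\Sigma_h = \alpha_{\Sigma h}(\delta_h^2 - \Sigma_h).$$

The variance gradients are rescaled by $\Sigma^2$ (this leaves their
fixed points untouched and keeps the updates well-behaved when a variance
is large), and both variances are floored at $0.2$. The valuation system,
being a critic rather than an actor, learns continuously throughout the
trial as described above.

Default parameters (`intensity_params()`, `td_params()`,
`dynamics_config()`): $\alpha_v = 0.5$, $\alpha_g = 0.05$,
$\alpha_h = 0.02$, $\alpha_{\Sigma g} = 0.05$, $\alpha_{\Sigma h} = 0.1$,
$\tau = 0.05$, $\tau_\delta = 0.02$, Euler step $10^{-3}$,
initialisation $q = w_j = 0.1$, $h = 0$, $\Sigma_g = 1$,
$\Sigma_h = 100$. The large initial habit variance is what makes early
behaviour goal-directed: the habit system's influence on planning grows
only as $\Sigma_h$ shrinks with experience.

## The two-action choice model

For choices between two actions the gains become matrices: $Q$ holds the
expected reward of action $i$ in state $j$ and $H$ the habit strength.
Planning adds mutual inhibition of strength `comp` between the two
intensities and clips them to $[0, 1]$; at the end of planning,
exploration noise of SD $\sigma_a = 2$ is added to each intensity and the
strongest entry is chosen, after which the action vector is binarised.
Outcome-phase dynamics are not integrated; prediction errors are
evaluated at their equilibria ($\delta_g = (r - Q_{ij})/\Sigma_g$ and the
scalar habit error $\delta_h = 1 - H_{ij}$) and parameters update once
per trial. Two habit-learning rules are available: the default vector
rule moves every row of $H$ toward the binarised action, and a
single-dopamine-signal approximation potentiates the chosen row while
depressing the other in proportion to its own strength; both keep $H$ in
$[0, 1]$. The variance update always uses the scalar error.

The choice model's initial conditions are not uniquely determined by the
published parameter set; habitsim uses $Q = 0.1$, $H = 0$, $\Sigma_g = 1$
and $\Sigma_h = 1$. The habit variance matters: with the intensity
model's $\Sigma_h = 100$ and the slow variance learning rate
($\alpha_\Sigma = 0.01$ per trial), $\Sigma_h$ would still be $\sim 20$
after 150 training trials, the habit drive $H/\Sigma_h$ would be
negligible, and none of the habit-system phenomena (habit dominance,
perseveration, post-reversal habit errors) could arise within the
protocol's trial counts. Starting at $\Sigma_h = 1$ the variance declines
during training as habits form, which is the regime the reversal
protocol probes.

A structural consequence of the printed exploration noise worth knowing:
with intensities clipped to $[0, 1]$ and independent $\mathcal N(0, 4)$
noise on each entry, choice accuracy cannot exceed
$\Phi(1/(2\sqrt2)) \approx 0.64$ no matter how well the contingency is
learned. Trained accuracy in the reversal protocol therefore sits near
0.6, and habit strengths differentiate to roughly $0.6$ vs $0.4$ rather
than $1$ vs $0$. Relatedly, with the per-trial variance learning rate of
$0.01$, $\Sigma_h$ reaches its pre-reversal equilibrium only after
several hundred trials; after the protocol's 150 training trials it is
still about twice that equilibrium, so the post-reversal rise in habit
prediction errors slows its decline rather than producing a clear
rebound. The elevated habit errors themselves, and the perseveration on
previously correct actions, are robust.

## Protocols

All five scripted experiments are driven by `experiment_spec()`, which
fills in the standard parameter values and validates overrides, and every
run is reproducible bit-for-bit from its spec and seed (a single RNG
stream; per trial the draw order is reward noise, then motor or choice
noise, then the stimulus).

* `run_acquisition()` — repeated intensity trials against the saturating
  schedule $r = 5\tanh(3a/5) - a + \mathcal N(0, 0.25)$, whose mean peaks
  at $a^* \approx 1.91$ with reward $\approx 2.17$. The valuation weight,
  habit gain and goal-directed gain converge near $2$, $2$ and $0.7$
  respectively (motor noise inflates $E[a^2]$ in the goal-directed
  fixed point $q^* = E[r\,a]/E[a^2]$, which holds $q^*$ below the
  noise-free value $\bar r/\bar a \approx 1$).
* `run_depletion_probe()` — clamps all dopaminergic signals
  ($\delta_v, \delta_g, \delta_h$) to zero on probe trials. Planning then
  reduces to $\tau\dot a = (hs - a)/\Sigma_h$: early in training the
  probe response collapses relative to the intact one, while after
  extended training the habit drives a near-intact response.
* `run_devaluation()` — trains for 120 or 360 trials, then removes the
  reward expectation (all $w_j$ and $q$ set to zero) and tests 180 trials
  in extinction ($r = -a$, the effort cost; learning stays on, so all
  groups extinguish). The devalued/control response ratio in the first
  30-trial bin is lower after moderate than after extended training — the
  habit signature. Devalued and control tests of a replicate share the
  training run and test noise (paired design).
* `run_pit()` — operant training (lever), Pavlovian conditioning of a
  separate stimulus (valuation learning only), then extinction testing
  with the conditioned stimulus co-presented on trials 21–30 and 41–50.
  On those trials the valuation sums both stimuli's values, so the actor
  plans a stronger response. Actor learning rates are lowered to
  $\alpha_g = 0.015$, $\alpha_h = 0.005$ for this protocol.
* `run_reversal()` — 150 trials of a two-stimulus/two-action contingency,
  then reversal, mean reward 1 for correct and 0 for error (noise SD
  0.5). Records per-trial choices, equilibrium errors, planning-phase
  error maxima and full parameter snapshots.

Each runner returns tidy tibbles (`tidy()`, `glance()`, `autoplot()`),
and `write_records()` emits a protocol-independent CSV schema plus a JSON
manifest.

```{r acquisition, eval = FALSE}
acq <- run_acquisition(experiment_spec("acquisition", seed = 1))
glance(acq)
autoplot(acq)
plot_trajectories(acq)
```

## What the synthetic protocols do and do not show

The environments are the idealised laboratory schedules: a stationary
saturating reward curve, binary-reward reversal, scripted devaluation and
transfer designs. They emulate the *contingencies* of the corresponding
animal experiments, not their richness: there are no inter-trial
dynamics (every trial restarts the within-trial state), no
satiety/motivation dynamics beyond the scripted zeroing of the reward
expectation, a single action dimension, and interval-based time coding
rather than realistic temporal basis functions. Passing tests therefore
show that the circuit-level mechanism produces the qualitative behavioural
and dopaminergic patterns under these contingencies — not that it fits
any particular animal's data quantitatively.

## Numerical notes and degenerate inputs

* Fixed-step explicit Euler everywhere (step $10^{-3}$, no adaptivity);
  `dt` may not exceed $\tau_\delta$, the fastest time constant.
* History buffers (for $v(t-I)$ and $e(t-I-3\tau)$) are zero-initialised
  each trial; trials are independent episodes.
* The lag $t - I - 3\tau$ is realised as `round((I + 3*tau)/dt)` buffer
  steps.
* Variance floors ($\Sigma \ge 0.2$) are enforced after every update;
  habit strengths in the choice model are clipped to $[0, 1]$ after every
  update, and action intensities to $[0, 1]$ after every integration step.
* `map_action()` signals an error when the posterior has no unique
  maximiser ($qs = 0$ with infinite habit variance); the trial loops
  signal divergence with the offending step if state becomes non-finite.
* Ties in the noisy argmax choice break toward the lower action index (a
  measure-zero event under Gaussian noise).
* The long-horizon behaviour of the intensity model is not stationary:
  because motor noise deflates the goal-directed gain below $v/\bar a$,
  the planned intensity drifts slowly upward past the reward optimum on
  timescales of $\sim 10^3$ trials. The published protocols (up to 540
  trials) operate well inside the stable window; the fragility of the
  parameter regime is a property of the model, not of this
  implementation.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script use the protocols at their
standard sizes (360-trial acquisition across 5 seeds; devaluation with 5
replicates; transfer with 10; 300-trial reversals across 3 seeds), with
the analytic-oracle suite (closed-form MAP action, temporal-difference
filter solution, Gaussian choice frequencies, bound/floor fuzzing) run at
100 random parameter draws.
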