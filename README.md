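# habitsim

Simulating dopaminergic prediction errors in action planning and habit
formation.

habitsim is an R package for computational neuroscientists studying how
the basal ganglia arbitrate between goal-directed and habitual control.
It implements a circuit-level model in which dopaminergic neurons in
distinct striatal territories encode distinct prediction errors, and
those errors do double duty: within a trial they drive the gradient
dynamics that *plan* an action, and between trials they gate the
three-factor plasticity that *learns* from its outcome.

## The model in brief

An actor chooses an action intensity `a` after observing a stimulus `s`,
given a reward expectation `v` supplied by a temporal-difference
valuation system. Two systems contribute, each encoding a Gaussian:

* goal-directed: reward likelihood `R ~ N(a q s, Σg)`;
* habit: action prior `a ~ N(h s, Σh)`.

The planned action maximises the posterior `P(a | R, s)`, i.e. the
objective

```
F = −(R − a q s)² / 2Σg − (a − h s)² / 2Σh − ½ ln Σg − ½ ln Σh
```

by gradient dynamics carried by prediction-error units,

```
τδ δ̇g = r + v − a q s − Σg δg        (reward prediction error, gain 1/Σg)
τδ δ̇h = a − h s − δh                 (non-habitual-action signal)
τ  ȧ  = δg q s + (h s − a) / Σh
```

so the plan converges to the precision-weighted MAP action
`a* = (q s R/Σg + h s/Σh) / ((q s)²/Σg + 1/Σh)`. After the outcome the
same errors, evaluated at the executed action, update the parameters
(`q̇ ∝ δg a s`, `ḣ ∝ δh s`, plus variance updates floored at 0.2), and a
continuous-time temporal-difference system with eligibility traces
updates the per-interval reward weights `w`. A two-action variant with
matrices `Q`, `H`, competitive planning dynamics and noisy argmax choice
covers reversal-learning experiments.

The within-trial integration (fixed-step Euler, dt = 0.001) runs in
compiled code; every step operation also has an exported R reference
implementation (`plan_step()`, `td_step()`, `learn_step()`, ...) that the
test suite checks against the compiled path and against closed-form
oracles.

## Worked example

A 360-trial acquisition run against the saturating reward schedule
`r = 5 tanh(3a/5) − a` (mean reward maximal, ≈ 2.17, at intensity
≈ 1.91):

```r
library(habitsim)

acq <- run_acquisition(experiment_spec("acquisition", seed = 1))
glance(acq)
#> # A tibble: 1 × 7
#>   n_trials    w1     q     h sigma_g sigma_h late_planned
#>      <int> <dbl> <dbl> <dbl>   <dbl>   <dbl>        <dbl>
#> 1      360  1.57 0.597  1.78   0.718    1.32         1.99
```

The valuation weight `w1` (reward expected right after the stimulus) and
the habit gain `h` converge near 2 — the reward available and the typical
intensity produced — while the goal-directed gain `q` settles around
0.6–0.9 so that `a·q·s` predicts the obtained reward; the planned
intensity ends near the reward-maximising 2. `autoplot(acq)` shows the
learning curves, `plot_trajectories(acq)` the within-trial dynamics of
`a`, `δv`, `δg`, `δh` on the recorded probe trials (trials 1, 120, 360),
which reproduce the classic patterns: the valuation error moves from
reward time to stimulus time over training; the goal-directed error rises
after the stimulus and is quenched as the plan forms; the habit error
flags non-habitual actions regardless of reward.

The other protocols follow the same pattern:

```r
run_depletion_probe(experiment_spec("depletion", seed = 1))$probes
#> # A tibble: 2 × 3
#>   trial planned_depleted planned_intact
#>   <int>            <dbl>          <dbl>
#> 1   120            0.751           2.74
#> 2   360            1.76            2.00
```

With all dopaminergic signals clamped to zero, the partially trained
model (trial 120) loses most of its response — planning is
dopamine-dependent — while the extensively trained model still responds
through its habit system. `run_devaluation()`, `run_pit()` and
`run_reversal()` reproduce the devaluation-by-training interaction,
Pavlovian-instrumental transfer, and post-reversal perseveration with
elevated habit prediction errors; see the vignette in `vignettes/` for
the science and the design decisions.

A thin command-line wrapper is installed at `inst/exec/habitsim`:

```sh
Rscript inst/exec/habitsim reversal --seed 3 --out out/   # records + manifest
Rscript inst/exec/habitsim selftest                        # analytic oracles
```

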