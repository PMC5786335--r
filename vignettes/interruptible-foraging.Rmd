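---
title: "Interruptible foraging under predation risk: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interruptible foraging under predation risk: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interforage)
```

## The decision problem

`interforage` studies a foraging animal that must decide not only *what*
to do but *for how long* to commit to doing it, when every deliberation
carries a cost. The environment has two locations: a **refuge** (safe,
no food) and a **patch** (food, but exposure to predation). Two hidden
binary variables evolve as independent telegraph processes:

* **predator**: absent ⇄ present with rates $\gamma_{AP}$ (arrival) and
  $\gamma_{PA}$ (departure), per second;
* **habitat quality**: good ⇄ bad with rates $\gamma_{GB}, \gamma_{BG}$.

The animal always knows its location but never observes the hidden
variables directly. Its information state is the belief pair
$(\beta^D(P), \beta^Q(G))$ — the posterior probabilities that the
predator is present and that the habitat is good — which, together with
location, is a sufficient statistic for optimal choice.

Actions are location-specific: `rest`, `assess`, `transit` in the
refuge; `feed`, `assess`, `freeze`, `escape` in the patch. A choice is
an **activity** $(a, \tau)$: an action plus a committed duration
$\tau$ drawn from a finite menu (1–15 s by default). Every decision
epoch charges a fixed **decision cost** $c_d$, the model's stand-in for
the computational and metabolic expense of deliberation. Rewards accrue
at per-second rates: feeding pays according to the encountered patch
(rich at rate $\rho_r$, poor at $\rho_p$, with rates conditioned on
habitat quality), `rest` is free, the remaining actions carry small
energetic costs, and being detected by the predator costs a one-off
penalty $r_{pred} = -100$. Detection while exposed is action-dependent
($\delta_{escape} \ge \delta_{transit} \ge \delta_{feed} > \delta_{assess}
> \delta_{freeze}$): freezing hides, assessment is relatively discreet,
and locomotion is conspicuous. Future rewards are discounted at rate
$\alpha = 0.1$ per second.

The defaults throughout (`model_params()`) are:
$\gamma_{AP} = \gamma_{PA} = 0.1$,
$\gamma_{GB} = \gamma_{BG} = 0.01$, indirect-cue rates
$\lambda_{o_i}^+ = 0.5 / \lambda_{o_i}^- = 0.1$, direct-cue rates
$\lambda_{o_d}^+ = 0.9 / \lambda_{o_d}^- = 0.1$, encounter rates
$\rho_{rG} = 0.8, \rho_{pG} = 0.2$ (mirrored in the bad habitat),
feeding rewards $2$ (rich) and $1$ (poor) per second,
$r_{transit} = r_{assess} = r_{freeze} = -0.1$, $r_{escape} = -1$,
$\delta_{feed} = \delta_{transit} = \delta_{escape} = 0.05$,
$\delta_{assess} = 0.02$, $\delta_{freeze} = 0.01$, $\Delta t = 1$ s,
$\Delta\beta = 0.01$.

## Observation model and belief filtering

Information arrives on channels gated by the current action:

* an **indirect cue** $o_i$ (a rustle in the bushes) is emitted at rate
  $\lambda_{o_i}^+$ when the predator is present and $\lambda_{o_i}^-$
  when absent; it is available during every action except `rest`;
* a **direct cue** $o_d$ is available only during `assess`, with rates
  $\lambda_{o_d}^\pm$ — assessment buys sharper evidence;
* the feeding outcome (rich/poor/none) is informative about habitat
  quality, and only available while feeding.

Between observations each belief component relaxes in closed form
toward its chain's stationary probability,

$$\beta^D_{t+\tau}(P) = \frac{\gamma_{AP}}{\gamma_{AP}+\gamma_{PA}}
 + \Big(\beta^D_t(P) - \frac{\gamma_{AP}}{\gamma_{AP}+\gamma_{PA}}\Big)
   e^{-(\gamma_{AP}+\gamma_{PA})\tau},$$

(`propagate_belief()`), and per step the filter uses the discrete
one-step prior (`propagate_belief_step()`), which is exactly the prior
of the discrete chain the simulator implements. Observations multiply
in as two-hypothesis Bayes factors with per-step emission probability
$\lambda \Delta t$; an *omission* of an available cue carries the
complementary likelihood $1 - \lambda \Delta t$. (The alternative
convention, using $\lambda^- \Delta t$ as the omission likelihood under
presence, makes the filter incoherent — likelihoods over outcomes of a
channel must sum to one under each hypothesis — so the complement is
used.) The test suite verifies the whole filter against a brute-force
two-state hidden-Markov forward pass on simulated trajectories.

One deliberate asymmetry: the filter conditions on cues and feeding
outcomes but **not** on having survived the step, mirroring the update
rules the model defines. Surviving an exposed step is, strictly, weak
evidence of absence; ignoring it makes the solved value a slight
overestimate of risk relative to realized trajectories (visible in the
single-location example, where simulated mean reward under the optimal
policy exceeds the solved value at the starting belief by ~20%). The
planner and the simulated agent share the same filter, so planner,
agent, and extracted thresholds are mutually consistent.

## Within-step event order

A single $\Delta t$ step of an activity unfolds as: (1) **detection**,
evaluated against the state at the step's start — the predator must
already be present — with probability
$\beta^D(P)\,(1 - e^{-\delta_a \Delta t})$ from the planner's
viewpoint; (2) the hidden **transitions**; (3) **cues and encounters**,
emitted from the post-transition state (matching the propagate-then-
update filter). Capture ends the activity, costs $r_{pred}$, relocates
the animal to the refuge, and the process continues — predation is an
injury, not death. The belief carried out of a capture is certainty of
presence propagated one step, $e^{-\gamma_{PA}\Delta t}$. Locations
change only when a `transit`/`escape` commitment *completes*; en route
the animal is exposed at that action's detection rate.

## Solving: value iteration over the belief grid

Beliefs are discretized at resolution $\Delta\beta$ on $[0,1]^2$.
`build_step_operator()` enumerates, at every grid point, every joint
step outcome with its exact path probability, posterior belief, and
reward, and assembles them into sparse matrices; posteriors are mapped
to the grid by bilinear interpolation by default (`grid_mode =
"nearest"` reproduces a severe discretization with its characteristic
ragged boundaries). Branch probabilities sum to one at every node by
construction, which the tests assert.

`value_iteration()` iterates
$V(b) \leftarrow \max_{(a,\tau)} \{-c_d + Q(b; a, \tau)\}$
to sup-norm tolerance $10^{-6}$, where $Q$ is computed by backward
recursion over the commitment's steps with per-step discount
$e^{-\alpha \Delta t}$. With **interruption**, the continuation at
every intermediate step is $\max(C_{k-1}, V)$: stopping is free, and
re-deciding is worth the decision value $V$ (which already carries
$c_d$). Only `feed`, `assess`, and `freeze` are interruptible:
`transit` and `escape` are ballistic relocations, and during `rest`
beliefs evolve deterministically, so nothing can be learned
mid-commitment that was not known at its start.

**Tie-breaking.** Free interruption makes $Q(a,\tau)$ weakly
nondecreasing and typically *flat* in $\tau$ beyond the point where an
interrupt would fire at once, so the argmax over durations is often a
tie. Ties are broken toward the *shortest* duration for ballistic
activities — preserving the result that with $c_d = 0$ every optimal
duration is minimal — and toward the *longest* duration for
interruptible activities in the interruptible regime, expressing the
strategy the solution embodies: commit provisionally for as long as
possible and rely on the interrupt. Across actions, ties fall to a
fixed canonical order. All of this makes solutions bit-reproducible.

## The single-location example

`solve_simple()` is a stripped-down, undiscounted, terminating
instance: one location, a predator that arrives (0.01/step) and stays,
catch probability 0.1/step while present (penalty −100, terminal),
`feed` (+1/step, indirect cues only), `assess` (0, direct + indirect
cues), `escape` (0, terminal). The cue rates are not part of the
original description beyond "poor" (+) versus "better" (++)
information; this implementation reuses the full model's rates
(0.5/0.1 indirect, 0.9/0.1 direct) as per-step probabilities. Under
those rates the zero-cost policy is `feed` on $\beta(P) \in [0,0.05]$,
`assess` on $[0.06, 0.77]$, `escape` above — the qualitative ordering
(feed when safe, assess under uncertainty, escape when threatened) with
a noticeably wide assess band: strong direct cues make information
cheap, which postpones escape. Weaker cue rates move the escape
boundary down.

## Simulation experiments

`run_trial()` executes a solved policy closed-loop against a scripted
predator schedule (the benchmark protocol: 2 min absent, 2 min
present, 2 min absent) with free-running habitat. Trials start in the
refuge, uninformed: beliefs at the hidden chains' equilibria
($(0.5, 0.5)$ under the defaults), with the true habitat drawn from
its stationary distribution. This initialization is what gives the
decision-cost sweep its characteristic return to ratio 1: once $c_d$
is large enough that the policy selects `rest` at the uninformed
belief, the trial never escapes it — `rest` yields no observations, so
the belief relaxes toward, and then sits at, equilibrium — and both
policies collapse to permanent rest with identical reward. An
alternative initialization that tells the animal the trial starts
predator-free keeps both policies foraging far beyond that point and
the ratio never reverts; the collapse cost should therefore be read as
a property of the policies *at the uninformed belief*, not of foraging
as such.

Every event channel (habitat flips, detection, each cue, encounters)
consumes its own uniform draw from a per-trial stream at every step,
whether or not the current action uses it, so two policies simulated
with the same seed face *identical* environments. This common-random-
numbers design makes the non-interruptible/interruptible reward ratio
exactly 1 when the policies coincide (as at $c_d = 0$) and removes
between-policy sampling noise everywhere else.
`compare_interruptibility()` sweeps $c_d$, re-solving both policies and
reporting the matched ratio, decision frequencies, and rest occupancy;
`behaviour_summary()` clamps the predator and reports occupancy,
activity budgets, and bout-length statistics (a bout being a maximal
run of the same action as an external observer would score it — bouts
of feeding far outlast the 1-s commitments because the policy
re-selects feeding).

## Threshold-based interruption

The exact interrupt rule compares the value of continuing against the
value of re-deciding at every step — itself a (costly) computation. The
cheap alternative: at an activity's outset, fix a **threshold** on
$\beta^D(P)$ and interrupt when it is crossed.
`extract_thresholds()` reads the boundary of the continue region off
the solved interruptible policy, at the full remaining commitment
$\tau_{max}$ (the duration at which interruptible activities are
initiated; empirically the continue region is insensitive to the
remaining duration). `feed` has only an upper boundary; `assess` has
both. `fit_linear_thresholds()` fits
$\theta \approx w_0 + w_1 \beta^Q(G) + w_2 c_d$ per boundary by
unweighted least squares, and `evaluate_approx_policy()` re-runs the
matched comparison with interruption triggered by the fitted planes
for `feed` and `assess` (`freeze`, whose initiation set is too sparse
to fit, keeps the exact test). Threshold crossings are evaluated at the
belief's nearest grid value, matching the exact rule's nearest-node
lookup; with thresholds fixed at the extracted optima the approximate
policy reproduces the exact interruptible metrics on matched streams
to well under 1%.

## What the generator does and does not emulate

The synthetic world implements exactly the model the solver assumes —
telegraph dynamics, Bernoulli/categorical per-step events, scripted
predator segments for protocols. Passing tests therefore demonstrate
internal consistency (solver ↔ simulator ↔ filter) and reproduction of
the model's published behavioural signatures; they say nothing about
real foragers, real predator dynamics (which respond to prey), spatial
structure, satiation, or resource depletion, all of which are outside
the model by design.

## Numerical choices

* Belief grid $\Delta\beta = 0.01$ (101 × 101 per location); value
  iteration tolerance $10^{-6}$ sup-norm, cap $10^4$ sweeps
  (convergence takes ~120–300 sweeps at the default discount).
* Bilinear value interpolation by default; nearest-node mode retained
  for reproducing severe-discretization behaviour.
* The simulated interrupt test uses a $10^{-7}$ slack so that exact
  value ties (ubiquitous at $c_d = 0$) never trigger gratuitous
  interrupts.
* Duration ties: shortest-first for ballistic, longest-first for
  interruptible activities; action ties in canonical order.
* Degenerate inputs: zero switching rates make propagation the
  identity; uninformative cues ($\lambda^+ = \lambda^-$) leave beliefs
  on their prior dynamics; beliefs at 0 or 1 are fixed points of the
  Bayes update.
* Test and example problem sizes: unit and property tests run at
  $\Delta\beta \in \{0.5, 0.1, 0.05\}$ with short duration menus; the
  full $\Delta\beta = 0.01$ configuration is exercised once in the
  acceptance suite and throughout `scripts/acceptance.R`, with the
  decision-cost sweep at 200 matched trials per cost.

## Known limitations

* The critical decision cost at which both policies collapse to
  permanent rest depends visibly on the grid mapping and resolution
  (coarser grids and interpolation both flatter the value of foraging),
  and on trial initialization; the package reports it under the nominal
  $\Delta\beta = 0.01$, truthful-initialization conditions.
* Thresholds are extracted at grid resolution, so fitted coefficients
  inherit a quantization error of order $\Delta\beta$.
* The filter's survival blind spot (above) means solved values are
  conservative relative to realized returns; all published comparisons
  are between policies under the same filter, so ratios are unaffected.
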