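---
title: "Optimized gamification of habit formation: model, engine, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized gamification of habit formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitpoints)
```

## The model

`habitpoints` treats habit formation as a one-dimensional Markov
decision process. The state is the habit strength $s \in [0, 1]$; the
action is enacting the intended behavior ($a = 1$) or not ($a = 0$).
One enactment closes a fraction $\alpha$ of the remaining gap to full
strength,

$$s' = s + \alpha\,(1 - s),$$

and one failure decays the strength proportionally, $s' = s(1 -
\alpha)$. The habit counts as cultivated once $s$ reaches a threshold
$\theta$, at which point a goal reward $r_\mathrm{goal}$ accrues.
Enacting costs effort $1 - s$ (strong habits are cheap to maintain);
skipping is free.

For a user who will follow through until the habit is formed, the
value-to-go of strength $s$ is the goal reward minus the remaining
effort along the enactment trajectory. Because the trajectory is
geometric, both the number of remaining enactments and the value have
closed forms:

$$n(s) = \left\lceil \frac{\log\{(1-\theta)/(1-s)\}}{\log(1-\alpha)}
\right\rceil, \qquad
V(s) = r_\mathrm{goal} - (1 - s)\,\frac{1 - (1-\alpha)^{n(s)}}{\alpha}.$$

The long-term benefit of an action is the induced value difference
$f(s, a) = V(s') - V(s)$ — a potential-based shaping term. For
enactment below the threshold it collapses analytically to $f(s, 1) =
1 - s$; for failure it is nonpositive and changes erratically wherever
$n(s)$ jumps. Scaling by a maximal point value $M$ and integerizing
gives the point feedback

$$\mathrm{points}(s, a) = \mathrm{int}\left(M \cdot f(s, a)\right),$$

which is what makes a *purely myopic* user's immediate incentives
agree with the long-run optimum: the points repay, today, exactly the
long-term value the action creates or destroys.

```{r}
params <- habit_params() # alpha 0.1, theta 0.9, M 13
compute_points(2 / 7, 1, params)
compute_points(2 / 7, 0, params)
n_to_goal(c(0.10, 0.09, 0.081, 0.08), params)
```

## Parameters and defaults

* `alpha = 0.1` — learning rate. One enactment closes 10% of the gap
  to full strength; one failure costs 10% of the current strength.
* `theta = 0.9` — target strength at which the habit counts as formed.
* `max_points = 13` — the scale on which benefits become points.
  These three defaults are the example application the package's
  worked numbers come from.
* `goal_reward = 0` — shifts every value by the same constant and
  cancels out of every point computation (a tested invariant); it only
  matters if you want values on an interpretable scale.
* `eps = 1e-12` — threshold-comparison tolerance (next section).

## Numerical choices

**Integerization.** The exact scaled failure benefit at $s = 2/7$ is
$M \cdot f(2/7, 0) \approx -4.52$. Rounding to nearest gives $-5$,
truncation toward zero gives $-4$ — and $-4$, together with the $+9$
for enacting, is the pair of integers the engine is meant to
reproduce. The default `rounding_mode` is therefore
`truncate_toward_zero`, with `nearest_half_away` available as an
option. Both modes agree on the enactment reward at that strength.

**Threshold semantics.** "Reaching" $\theta$ is tested as $s \ge
\theta - \varepsilon$ with $\varepsilon = 10^{-12}$, so a trajectory
that lands within floating-point noise of the threshold counts as
arrived. The closed-form $n(s)$ is first evaluated with an
$\varepsilon$ guard inside the ceiling and then adjusted against the
exact post-$n$ strength, so ties on the ceiling boundary always
resolve to the iterative definition. `verify_closed_forms()` checks
this agreement — count, value, and the $f(s,1) = 1-s$ identity —
against deliberately independent brute-force iteration; the oracle
code shares no lines with the closed forms, and its iteration cap
(10^6) exists because $n$ diverges as $\alpha \to 0$.

**At and above the threshold.** $V(s) = r_\mathrm{goal}$ for $s \ge
\theta$, so $f(s, 1) = 0$ and feedback is 0 points; the engine keeps
running rather than terminating. Strength keeps obeying the update
rules after crossing — a failure can drop it back below $\theta$, at
which point penalties resume. Onboarding with a 7/7 week initializes
$s = 1$ and is allowed; it simply yields 0-point feedback.

**Order of operations.** Points are computed on the strength *in
which the action was taken*; the strength update is applied
afterwards. Scores start at 0 by default and may go negative.

## The myopic-agent simulator

`simulate_trial()` is the package's fixture generator and the testbed
for the incentive-alignment property. It emulates a three-arm design:
an optimized-points arm, a text-feedback arm (reminders and rotating
texts, no points), and a bare baseline (neutral "OK", no reminders).
Each simulated user is myopic: the immediate utility of enacting is
$-w\,(1 - s) + v \cdot \mathrm{feedback}(s, 1)$ against $v \cdot
\mathrm{feedback}(s, 0)$ for skipping, with a logistic choice rule of
slope $\beta$ ($\beta = \infty$ means argmax).

The utility model and its defaults ($v = 0.15$, $w = 1$, $\beta = 3$,
text bonuses $+1/0$) are this package's own construction — the study
being emulated reports no behavioral model of its participants. The
defaults were chosen once so that all three arms produce interior,
non-degenerate enactment rates; they are not fitted to anything, and
any resemblance of simulated arm means to field data would be
coincidental. What the simulator *does* establish, exhaustively over
a strength grid, is the design property: with deterministic choice
and unit weights, the optimized-arm agent enacts at every
pre-threshold strength while the baseline agent never does.

Initial strengths are drawn as $k/7$ with $k$ uniform on $\{0,\dots,
4\}$, mirroring the support of the onboarding question. Each
participant runs on an RNG substream derived from the root seed, the
arm, and the participant index, so enlarging an arm never reshuffles
earlier participants.

Simulated agents are stationary and perfectly compliant reporters;
real participants drop out, mis-report, and change over time. Passing
trial-level tests therefore demonstrates properties of the incentive
mechanism, not predictions about human enactment counts.

## The session engine

`onboard()`, `daily_step()`, and `run_session()` reimplement the
chatbot's conversational logic transport-free: time is a day index
plus clock-time labels (reminders nominally at 21:00, check-ins 0.5
to 2.5 hours after the trigger moment), and no scheduler or messaging
platform is attached. The log is append-only and event-sourced:
`replay_log()` rebuilds the final state from the onboarding and
report events alone and must agree exactly with the incrementally
maintained state — a property tested over thousands of random report
sequences.

Open points the engine had to decide:

* Only two of the eight trigger moments and one of the five rotating
  congratulatory phrases are published; the rest are clearly marked
  placeholders in `default_trigger_moments()` and
  `default_message_templates()` and are fully configurable.
* Whether the phrase rotation was deterministic or random is not
  documented; the engine cycles deterministically (index = count of
  positive messages mod 5). This affects no scores.
* Unanswered check-ins are not specified; the engine applies no state
  change and logs an explicit report gap, so missing days are visible
  in the log but never penalized.

## Problem sizes used in the test suite

The oracle-equivalence checks run on 1000-point strength grids for
nine $(\alpha, \theta)$ combinations; the incentive-alignment check
is exhaustive on a 100-point grid; event-sourcing consistency runs
1000 random sessions of up to 21 days; trial sanity uses 10 root
seeds at 50 participants per arm over 21 days. All of it completes in
well under a minute on one core.

## Limitations

* The model has no lapse dynamics after the habit is formed and no
  explicit health-state variable; the state is habit strength alone.
* $\alpha$ and $\theta$ are fixed per deployment, not learned per
  user.
* The value model prices only the enact-always trajectory; it is not
  a general MDP solver, because with two actions and a one-dimensional
  state nothing more is needed.
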