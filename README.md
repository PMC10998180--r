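# habitpoints

Incentive design for digital behavior-change interventions.
`habitpoints` models habit formation as a one-dimensional Markov
decision process and converts value-to-go differences into the integer
point rewards and penalties a chatbot or habit tracker should show its
users — so that even a purely myopic user, who cares only about
today's payoff, is steered toward the actions that are best in the
long run. It is aimed at researchers and developers of gamified
behavior-change tools who want principled rather than ad hoc point
values.

## The model

Habit strength $s \in [0,1]$ is the state. Enacting the behavior
($a=1$) updates $s \leftarrow s + \alpha(1-s)$ at effort cost $1-s$;
failing ($a=0$) decays $s \leftarrow s(1-\alpha)$ for free. The habit
counts as formed when $s$ reaches a threshold $\theta$, earning
$r_\mathrm{goal}$. For a user who follows through, the value-to-go is

$$V(s) = r_\mathrm{goal} - (1-s)\,\frac{1-(1-\alpha)^{n(s)}}{\alpha},
\qquad
n(s) = \left\lceil\frac{\log\{(1-\theta)/(1-s)\}}{\log(1-\alpha)}\right\rceil,$$

and each action is scored by its long-term benefit $f(s,a) = V(s') -
V(s)$ (for enactment this collapses to $1-s$), scaled by a maximal
point value $M$ and integerized:

$$\mathrm{points}(s,a) = \mathrm{int}\{M \cdot f(s,a)\}.$$

The package provides this engine (`compute_points()`, `n_to_goal()`,
`value_to_go()`, `point_curve()`), a brute-force oracle that verifies
every closed form (`verify_closed_forms()`), a myopic-agent simulator
with a three-arm synthetic trial (`simulate_trial()`), a
transport-agnostic chatbot session engine with event-sourced JSONL
logs (`onboard()`, `daily_step()`, `replay_log()`), and a small CLI
(`habit_cli()`, `inst/scripts/habitbot.R`).

## Worked example

A user who drank water on 2 of the previous 7 days starts at strength
2/7. With the default parameters ($\alpha=0.1$, $\theta=0.9$, $M=13$):

```r
library(habitpoints)
params <- habit_params()

compute_points(2/7, 1, params)
#> [1] 9
compute_points(2/7, 0, params)
#> [1] -4
```

Enacting earns 9 points (13 times the remaining benefit $1 - 2/7$,
truncated); failing loses 4 (the value destroyed by the decay to
$0.9 \cdot 2/7$, scaled and truncated). The penalty is nonmonotone in
strength because the enactments-to-goal count jumps:

```r
n_to_goal(c(0.10, 0.09, 0.081, 0.08), params)
#> [1] 21 21 22 22
```

A failure at 0.09 pushes the count from 21 to 22, while at 0.10 or
0.08 a failure leaves it unchanged. A full chatbot session, with the
score ledger and message texts:

```r
s <- run_session(c(1, 0, 1), trigger_choice = default_trigger_moments()[2],
                 amount = 1.5, days_last_week = 2,
                 config = session_config("optimized"))
s
#> <habit_session> optimized arm, day 3, strength 0.3893, score 12
#>   14 log events
cat(s$messages, sep = "\n")
#> Did you accomplish your goal today to drink 1.5 glasses of water?
#> Great job!
#> I am glad to grant you 8 points for keeping a good habit! Your total score is 12 points
#> Remember your intention: when I have the first bite of my lunch, I will drink 1.5 glasses of water
```

`replay_log(s$log, config)` rebuilds that state from the log alone,
and `simulate_trial(trial_config())` runs the three-arm synthetic
trial in which optimized points reliably out-motivate the no-feedback
baseline for simulated myopic users.

## Command line

```sh
Rscript inst/scripts/habitbot.R points --strength 0.2857142857 --action 1   # 9
Rscript inst/scripts/habitbot.R curve --out curve.csv
Rscript inst/scripts/habitbot.R verify
Rscript inst/scripts/habitbot.R simulate-trial --seed 1 --out trial.csv
```

See `vignettes/optimized-gamification.Rmd` for the model's
assumptions, the numerical decisions (rounding mode, threshold
tolerance), and what the simulator does and does not establish.
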