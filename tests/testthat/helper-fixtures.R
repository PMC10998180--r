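# Shared fixtures: the example application's parameters and small
# parameter sweeps used by the property tests.
default_params <- habit_params() # alpha 0.1, theta 0.9, M 13

param_sweep <- function(alphas = c(0.05, 0.1, 0.3),
                        thetas = c(0.8, 0.9, 0.95)) {
  expand.grid(alpha = alphas, theta = thetas)
}

# Deterministic always-follow-through profile used in the
# incentive-alignment checks.
argmax_profile <- function() {
  agent_profile(point_utility = 1, effort_weight = 1,
                choice_sharpness = Inf)
}
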