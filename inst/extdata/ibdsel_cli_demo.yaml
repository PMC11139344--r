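# Minimal end-to-end configuration for the command-line interface demo
lattice:
  dims: [9]
patch_size: 5
dispersal:
  type: truncated_binomial
  move_prob: 0.5
  mean_distance: 1.5
commons_movement:
  type: truncated_binomial
  move_prob: 0.6
  mean_distance: 1.5
payoff:
  B: 2
  alpha_B: 1
  C: 1
  alpha_C: 4
environment:
  epsilon: 0.5
  production_slope: 5
lifecycle: wf_fecundity
simulation:
  generations: 50
  burn_in: 10
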