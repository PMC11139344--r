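# Reduced simulation configuration: 7 x 7 lattice of 20 adults with the
# same payoff structure as the large spite setting, commons movement
# scaled to the smaller torus.
lattice:
  dims: [7, 7]
patch_size: 20
dispersal:
  type: truncated_binomial
  move_prob: 0.3
  mean_distance: 1.5
commons_movement:
  type: truncated_binomial
  move_prob: 1.0
  mean_distance: 5
payoff:
  B: 2
  alpha_B: 1
  C: 1
  alpha_C: 4
environment:
  epsilon: 0.5
  production_slope: 20   # P(z) = N z
lifecycle: wf_fecundity
simulation:
  generations: 4000
  burn_in: 1000
  mutation_prob: 1.0e-4
  mutation_sd: 1.0e-2
  init_trait: zstar
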