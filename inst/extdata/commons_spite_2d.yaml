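# Full lasting-commons model on a 13 x 13 lattice of 50 adults:
# short-range species dispersal, full long-range commons movement.
# The dispersal asymmetry puts this configuration in the spite regime
# (Omega < 0).
lattice:
  dims: [13, 13]
patch_size: 50
dispersal:
  type: truncated_binomial
  move_prob: 0.3
  mean_distance: 1.54
commons_movement:
  type: truncated_binomial
  move_prob: 1.0
  mean_distance: 8
payoff:
  B: 2
  alpha_B: 1
  C: 1
  alpha_C: 4
environment:
  epsilon: 0.5
  production_slope: 50   # P(z) = N z
lifecycle: wf_fecundity
simulation:
  generations: 20000
  burn_in: 5000
  mutation_prob: 1.0e-4
  mutation_sd: 1.0e-2
  init_trait: zstar
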