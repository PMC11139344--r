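# 1D toy lattice: 7 patches of 5 adults, moderate short-range dispersal
lattice:
  dims: [7]
patch_size: 5
dispersal:
  type: truncated_binomial
  move_prob: 0.5
  mean_distance: 1.5
lifecycle: wf_fecundity
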