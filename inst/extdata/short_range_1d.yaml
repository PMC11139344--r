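# 1D lattice, 51 patches of 20 adults, short-range dispersal
lattice:
  dims: [51]
patch_size: 20
dispersal:
  type: truncated_binomial
  move_prob: 0.8
  mean_distance: 1.9
lifecycle: wf_fecundity
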