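# Optimal packaged length for the CCMV parameterization, base-paired cargo.
name: ccmv_leq
method: equilibrium_length
capsid:
  preset: CCMV          # T=3, Rin 11.5 nm, ARM 48 / +10
polymer:
  type: base_paired
  LC: 6000
  fbp: 0.5
  Lbp: 5
  normalized_mld: 0.5
run:
  dt: 1.0e-4
  n_steps: 1.0e+7
  box: 0
  n_seeds: 3
  permeable_subunit: 1
expected:
  leq_nt: 3136
  genome_nt: 3233
  occupied_volume_fraction: 0.099
  tolerance: 0.05
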