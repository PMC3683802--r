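# Subunit dimerization free energy versus attraction strength; single
# attractive edge limits complexes to dimers.
name: dimer_eps_scan
method: dimer_binding
epsilon_grid: [4, 5, 6, 7, 8, 9, 10]
run:
  dt: 1.0e-4
  n_steps: 1.0e+8
  box: 200
  out_stride: 10000
expected:
  kd_at_eps5_molar: 0.33
  gcc_at_eps5_kBT: -1.1
  linear_fit: "gcc ~ -1.5 eps - T sb with sb = -9 kBT"
  armfree_gcc_at_eps5_kBT: -1.84
  arm_penalty_kBT: 0.74
  tolerance: 0.1
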