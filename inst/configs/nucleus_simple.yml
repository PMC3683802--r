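# Critical nucleus size from committor statistics at polymer length 575.
name: nucleus_simple
method: run_assembly + critical_nucleus
polymer_length: 575
run:
  dt: 1.0e-4
  n_steps: 2.0e+8
  box: 200
  n_subunits: 12
  trajectories: 20
expected:
  n_nuc: 5
  adsorbed_before_nucleation: 8   # mean subunits adsorbed pre-nucleus
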