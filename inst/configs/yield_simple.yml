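# Dynamical assembly yield around a linear polyelectrolyte at the optimum.
name: yield_simple
method: run_assembly + classify_outcome
capsid:
  preset: simple
polymer_lengths: [300, 400, 500, 550, 575, 600, 700, 900, 1200]
run:
  dt: 1.0e-4
  n_steps: 2.0e+8
  box: 200              # 12 subunits = 12 uM
  n_subunits: 12
  trajectories_per_length: 10
forcefield:
  epsilon: 5.0
  lambda_D: 1.0
expected:
  yield_at_575: 0.9
  tolerance: 0.1
  multiplets_at_1200: ">= 2 capsids on one polymer"
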