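# Optimal packaged length of the simple capsid via the semipermeable subunit.
name: leq_simple
method: equilibrium_length
capsid:
  preset: simple        # T=1, Rin 7.3 nm, ARM 5 x +1
polymer:
  type: linear
  length: 1000          # well above the expected optimum
forcefield:
  lambda_D: 1.0
run:
  dt: 1.0e-4
  n_steps: 1.0e+7       # "at least 1e7 steps", equilibrium by convergence
  box: 0
  out_stride: 10000
  n_seeds: 3
  permeable_subunit: 1
expected:
  leq_segments: 574
  tolerance: 0.02       # relative; standard error from >= 3 seeds
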