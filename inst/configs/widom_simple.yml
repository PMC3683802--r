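# Residual chemical potential curves (free vs encapsidated) and their
# intersection for the simple capsid model.
name: widom_simple
method: chemical_potential_curve
np_grid: [25, 50, 100, 200, 300, 400, 450, 500, 525, 550, 575, 600, 650]
protocol:
  n_relax: 1.0e+5       # dynamics steps between chain increments
  n_insertions: 1.0e+5  # insertions per Np
  n_runs: 100           # independent runs
contexts: [free, encapsidated]
expected:
  intersection_segments: [550, 575]
  encapsidation_dG_kBT: -500    # integral of the difference over [0, 575]
  dG_tolerance: 0.1
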