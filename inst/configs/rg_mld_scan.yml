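# Solution radius of gyration versus normalized maximum ladder distance for
# 1000-nt model NAs with 50% base-pairing.
name: rg_mld_scan
method: lambda_for_mld + mc_polymer_sampler
structure:
  LC: 1000
  fbp: 0.5
  Lbp: 5
normalized_mld_grid: [0.15, 0.25, 0.36, 0.5, 0.67, 0.8, 1.0]
sampling:
  n_moves: 2.0e+6
  n_seeds: 5
expected:
  rg_range_nm: [8, 20]
  power_law: "RG = 1.7 * MLD^0.43"
  exponent: 0.43
  linear_reference_rg_nm: 25.5
  rg_at_nmld_0.25_nm: 10.1
  tolerance: 0.1
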