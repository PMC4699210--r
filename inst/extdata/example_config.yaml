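# Example end-to-end configuration (scaled down for a quick run).
# Run with: mitopop::run_from_config(<this file>, output_dir = "results/run")
version: 1
seed: 1
simulate:
  genome_length: 16702
  n_group1: 10
  n_group2: 6
  n_diagnostic: 40
  n_diagnostic_indels: 2
  theta_within: 8
  coverage_mean: 120
caller:
  min_coverage: 4
  posterior_threshold: 0.95
regions:
  partial_offset: 400
  partial_length: 353
n_perm: 200
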