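# Example pipeline configuration: synthetic dataset under the default
# study conditions, all five responses, report written to results/report.
synthetic:
  n_species: 406
  seed: 1
responses: [diversity, total_tgcn, median_eps, gc_ending_diversity, at_ending_diversity]
out_dir: results/report
seed: 1
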