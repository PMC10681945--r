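# Example pipeline configuration. With `simulate` present the input
# tables are generated; replace it with `subjects:`/`items:` paths to
# run on real recall tables in the documented schema.
simulate:
  n_subjects: 5000
  seed: 1
n_cycles: 1
scope: all_caloric
output_dir: milksub-run
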