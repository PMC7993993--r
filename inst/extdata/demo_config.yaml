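# Demo pipeline configuration: small synthetic wild-type dataset through
# every stage. Run with
#   Rscript -e 'pomogram::run_pipeline("inst/extdata/demo_config.yaml")'
# (set out_dir to a writable location first), or via the CLI wrapper:
#   inst/exec/pomogram run --config inst/extdata/demo_config.yaml --out /tmp/demo
out_dir: pomogram_demo_out
seed: 1
simulate:
  preset: WT
  n: 50
  pixel_size: 0.1
  noise_sd: 0.1
cells:
  minicell_cutoff: 2.0
  constriction_depth: 0.10
clusters:
  k_sigma: 2
  min_width_segments: 2
  nucleoid_span: 0.8
demograph:
  bin_size: 0.1
timelapse:
  fission_probability: 0.8
  n_divisions: 50
  frame_interval: 20
atpase:
  preset: pomx_wt
  window: [300, .inf]
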