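# Small demonstration configuration for run_pipeline(): two subjects, two
# 20-second segment pairs per condition, full stage list.  The scientific
# defaults (5 subjects x 3 pairs x 50 s) are what the package's recovery
# experiments use; this file is sized for a quick interactive run.
seed: 7
n_subjects: 2
segments_per_condition: 2
duration: 20
off_ratios:
  ctx_stn: 1.5
  gpe_stn: 1.5
  stn_gpi: 1.5
stages: [simulate, features, invert, group, contribute, lesion]
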