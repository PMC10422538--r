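# Reference harmaline scenario: overrides shown explicitly, all other
# parameters take package defaults (see default_config()).
seed: 1
timecourse:
  t_baseline_end: 1800        # 30 min baseline, seconds
  peak_fractional_increase: 1.6
session:
  n_ensembles: 70
  time_compression: 60
ephys:
  enabled: true
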