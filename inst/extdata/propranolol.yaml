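# Suppression arm: tremorgen at 30 min, suppressor 20 min later.
seed: 1
timecourse:
  suppression_enabled: true
  t_suppressor: 3000
  suppression_depth: 0.8
  rebound_tau: 600
session:
  n_ensembles: 70
  time_compression: 60
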