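# Full pipeline configuration for the packaged plate study fixtures.
material: material_ti64_eli.json
sn_curve:
  Cf: 1.0
  Nc1: 1000000
prediction:
  N_max: 100000
  corrections: [goodman, gerber]
  extrapolate_low_cycle: false
fit:
  runout_policy: as_failure
  min_failures: 3
load_cases: load_cases_elastic.csv
observations: plate_campaign.csv
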