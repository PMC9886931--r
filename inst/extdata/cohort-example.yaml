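# Example synthetic-cohort configuration (overrides the built-in panel).
n_patients: 120
year: 2020
groups:
  - label: non-diabetic
    fraction: 0.57
  - label: diabetic
    fraction: 0.43
    offset_lcv: [0.049, 0.009, 0.021, 0.034, 0.005, -0.006]
seasonal:
  SBP:
    amplitude: 3.9
    peak_month: 2
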