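# SYNTHETIC placeholder normative table -- NOT a published norm.
# Replace these values with the age-referenced SDNN norms your study
# adopts (and record that choice in source_label) before interpreting
# SDNN deviations. Bands are [age_lo, age_hi); the last band is closed.
source_label: "synthetic placeholder (round numbers, operator must replace)"
bands:
  - {age_lo: 17, age_hi: 22, sdnn_norm_ms: 60}
  - {age_lo: 22, age_hi: 31, sdnn_norm_ms: 55}
  - {age_lo: 31, age_hi: 45, sdnn_norm_ms: 48}
  - {age_lo: 45, age_hi: 70, sdnn_norm_ms: 40}
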