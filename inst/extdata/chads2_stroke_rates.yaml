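# Annual ischemic-stroke rates on aspirin by CHADS2 score.
# External-sourced default grid (published per-score validation rates);
# replace with cohort-specific rates as needed.  Rates are fractions/yr.
levels:
  - {label: "0", p_stroke_aspirin: 0.019}
  - {label: "1", p_stroke_aspirin: 0.028}
  - {label: "2", p_stroke_aspirin: 0.040}
  - {label: "3", p_stroke_aspirin: 0.059}
  - {label: "4", p_stroke_aspirin: 0.085}
  - {label: "5", p_stroke_aspirin: 0.125}
  - {label: "6", p_stroke_aspirin: 0.182}
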