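# Base-case model configuration.  Every key mirrors a field of
# default_parameters(); omitted keys take the packaged defaults, so this
# file restates the full base case explicitly for reference.
# Probability-like keys may be written as percent strings ("4.5%").
p_stroke_aspirin: 0.045
rr_stroke_warfarin: 0.48
p_bleed_warfarin: 0.025
rr_bleed_aspirin: 0.59
frac_ich: 0.2
frac_fatal_stroke_warfarin: 0.082
frac_fatal_stroke_aspirin: 0.179
frac_fatal_ich: 0.364
frac_fatal_bleed_excl_ich: 0.049
cost_warfarin_annual: 180
cost_aspirin_annual: 10
cost_fatal_stroke_once: 12130
cost_stroke_once_warfarin: 9667
cost_stroke_monthly_warfarin: 2652
cost_stroke_once_aspirin: 9610
cost_stroke_monthly_aspirin: 2168
cost_ich_once: 31810
cost_ich_monthly: 4690
cost_bleed_excl_ich_once: 3620
cost_genetic_test: 100
u_well_warfarin: 0.987
u_well_aspirin: 0.998
u_stroke_warfarin: 0.476
u_stroke_aspirin: 0.426
u_ich: 0.4
u_recurrent_stroke: 0.12
u_dead: 0
cohort_size: 1000
horizon_cycles: 5
discount_rate: 0.03
test_positive_fraction: 0.40
p_convert_base: 0.025
conv_mult_test_positive: 2.0
conv_mult_test_negative: 0.5
wtp_per_qaly: 50000
ranges:
  p_stroke_aspirin: [0.03, 0.06]
  rr_stroke_warfarin: [0.37, 0.63]
  p_bleed_warfarin: [0.02, 0.04]
  rr_bleed_aspirin: [0.50, 0.70]
  cost_genetic_test: [50, 200]
  cost_multiplier: [0.5, 1.5]
  utility_multiplier: [0.8, 1.2]
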