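# Synthetic cohort emulating the SCT-like trial: n = 370, variable
# follow-up uniform(1/12, 1) years (fit with a person-time offset),
# baseline rate 0.83 falls/person-year, NB2 dispersion 0.66.
# Level probabilities are approximations chosen so the mean prior-fall
# count is 1.45; they are not published values.
label: sct
'n': 370
category_probs:
- 0.4133333333333333
- 0.25
- 0.12
- 0.08
- 0.05
- 0.0866666666666667
baseline_rate: 0.83
rate_ratios:
- 1.0
- 1.0
- 1.07
- 2.18
- 3.09
- 7.39
theta: 0.66
exposure:
  model: uniform
  min: 0.0833333333333333
  max: 1.0
tail_geometric_p: 0.5
seed: 22240333
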