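# Synthetic cohort emulating the KFPS-like trial: n = 855, fixed 12-month
# follow-up, baseline rate 0.61 falls/person-year, NB2 dispersion 1.18.
# Level probabilities are approximations chosen so the mean prior-fall
# count is 0.73; they are not published values.
label: kfps
'n': 855
category_probs:
- 0.6483333333333333
- 0.18
- 0.08
- 0.04
- 0.02
- 0.0316666666666667
baseline_rate: 0.61
rate_ratios:
- 1.0
- 1.46
- 1.65
- 2.98
- 6.24
- 7.4
theta: 1.18
exposure:
  model: fixed
  value: 1.0
tail_geometric_p: 0.5
seed: 23240336
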