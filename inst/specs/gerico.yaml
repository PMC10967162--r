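# Synthetic cohort emulating the GERICO-like study: n = 630, fixed 12-month
# follow-up, baseline rate 0.43 falls/person-year, NB2 dispersion 1.06.
# Level probabilities are approximations chosen so the mean prior-fall
# count is 1.03; they are not published values.
label: gerico
'n': 630
category_probs:
- 0.56
- 0.2
- 0.1
- 0.05
- 0.03
- 0.06
baseline_rate: 0.43
rate_ratios:
- 1.0
- 1.64
- 1.13
- 2.55
- 2.33
- 10.02
theta: 1.06
exposure:
  model: fixed
  value: 1.0
tail_geometric_p: 0.5
seed: 21240330
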