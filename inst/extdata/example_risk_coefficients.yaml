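# Synthetic illustrative coefficient set for the logistic risk model.
# These are NOT published PLCOm2012 coefficients; supply your own file with
# the same structure for a validated model.
intercept: -6.0
terms:
  - name: age
    transform: centered
    center: 62
    coefficient: 0.08
  - name: is_current_smoker
    transform: indicator
    coefficient: 0.8
  - name: is_former_smoker
    transform: indicator
    coefficient: 0.4
  - name: intensity
    transform: linear
    coefficient: 0.02
  - name: duration
    transform: linear
    coefficient: 0.03
  - name: family_history_lung_cancer
    transform: indicator
    coefficient: 0.6
  - name: copd
    transform: indicator
    coefficient: 0.5
  - name: bmi
    transform: centered
    center: 27
    coefficient: -0.03
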