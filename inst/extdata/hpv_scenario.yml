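'n': 2386
baseline:
  breaks: []
  rates: 0.0446287
factors:
  hivcd4:
    levels:
    - HIV-
    - CD4>500
    - CD4 200-500
    - CD4<200
    probs:
    - 0.3
    - 0.28
    - 0.28
    - 0.14
    reference: HIV-
  smoking:
    levels:
    - never
    - former
    - current
    probs:
    - 0.45
    - 0.25
    - 0.3
    reference: never
effects:
  hivcd4=CD4>500:
    breaks: []
    rates: 0.0343
  hivcd4=CD4 200-500:
    breaks: []
    rates: 0.0779
  hivcd4=CD4<200:
    breaks: []
    rates: 0.1395
  smoking=former:
    breaks: []
    rates: 0.0034
  smoking=current:
    breaks: []
    rates: 0.0224
visit_interval: 0.5
max_followup: 10.0
dropout_rate: 0.05
observation: visits
seed: 1
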