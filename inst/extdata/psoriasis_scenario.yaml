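# Psoriasis-like synthetic scenario: cohort class frequencies follow the
# published psoriasis case/control distributions, with a -0.12 copy-unit
# differential shift applied to case samples (the measured case/control
# class-2 means were 1.91 vs 2.03).
simulate:
  controlFrequencies:
    "0": 0.0150943396
    "1": 0.2113207547
    "2": 0.5396226415
    "3": 0.1849056604
    "4": 0.0415094340
    "5": 0.0075471698
  caseFrequencies:
    "0": 0.0307692308
    "1": 0.1282051282
    "2": 0.5897435897
    "3": 0.2307692308
    "4": 0.0102564103
    "5": 0.0102564102
  nCases: 195
  nControls: 265
  biasShift: -0.12
alpha: 0.05
seed: 20
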