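name: baseline
seed: 42
days:
  - train: [{seq: ABCDE, trials: 10}]
    evening_tests: [A]
  - morning_tests: [A]
  - morning_tests: [A]
  - morning_tests: [A]
  - morning_tests: [A]
nights: [1, 2, 3, 4]
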