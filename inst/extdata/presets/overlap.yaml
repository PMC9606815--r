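name: overlap
seed: 42
days:
  - train: [{seq: ABCDE, trials: 10}, {seq: FGCIJ, trials: 10}]
    evening_tests: [A, F]
  - train: [{seq: ABCDE, trials: 10}, {seq: FGCIJ, trials: 10}]
    evening_tests: [A, F]
  - train: [{seq: ABCDE, trials: 10}, {seq: FGCIJ, trials: 10}]
    evening_tests: [A, F]
  - train: [{seq: ABCDE, trials: 10}, {seq: FGCIJ, trials: 10}]
    evening_tests: [A, F]
nights: [1, 2, 3, 4]
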