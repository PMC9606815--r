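name: salience_two_seq
seed: 42
days:
  - train: [{seq: ABCDE, trials: 10}, {seq: FGHIJ, trials: 10}]
  - train: [{seq: ABCDE, trials: 10}]
  - train: [{seq: ABCDE, trials: 10}]
  - train: [{seq: ABCDE, trials: 10}]
nights: [1, 2, 3, 4]
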