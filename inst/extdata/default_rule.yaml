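# Default count-to-interval grading rule.
# I = papule + pustule count, N = nodule/cyst count.
# Rows are matched first to last; absent bounds are unbounded.
- when: {N_min: 2}
  interval: [6, 8]
- when: {N_min: 1, N_max: 1}
  interval: [5, 7]
- when: {N_min: 0, N_max: 0, I_min: 30}
  interval: [5, 6]
- when: {N_min: 0, N_max: 0, I_min: 15, I_max: 29}
  interval: [4, 5]
- when: {N_min: 0, N_max: 0, I_min: 5, I_max: 14}
  interval: [3, 4]
- when: {N_min: 0, N_max: 0, I_min: 1, I_max: 4}
  interval: [2, 3]
- when: {N_min: 0, N_max: 0, I_min: 0, I_max: 0}
  interval: [1, 2]
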