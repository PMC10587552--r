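# Quickstart experiment: small synthetic benchmark on one CPU.
dataset:
  n_subjects: 60
  side_px: 64
  train_frac: 0.75
detector:
  score_threshold: 0.2
  iou_threshold: 0.5
counts_source: truth
grader:
  epochs: 40
  batch_size: 16
  hidden: 32
  grid: 8
  resize_side: 64
  input_side: 56
panel:
  n_raters: 7
  noise_sd: [0.2, 0.5, 0.8, 1.1, 1.4, 1.7, 2.0]
  bias: [0, 0, 0, 0, 0, 0, 0]
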