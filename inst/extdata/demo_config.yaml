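# Demonstration run: 15 mice, six barcodes at the half-loss spike-in for a
# true colonization probability of 0.03, untagged bulk dose 1e7 CFU.
experiment:
  n_mice: 15
  barcode_means: [23, 23, 23, 23, 23, 23]
  untagged_dose: 1.0e7
strain:
  q: 0.03
  r: 0.62
  c: 0.0
  tau: 3.2
state:
  K: 1.0e10
  t_tot: 48
measurement:
  detection_limit: 30
  qpcr_cv: 0.1
seed: 1
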