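# Desk-scale smoke experiment: small cohort, short schedules.
seed: 7
n_ecg_subjects: 10
n_paired_subjects: 21
duration_s: 20
repr_frac: 0.5
k_folds: 7
ecg_vae:
  epochs: 6
radio:
  epochs: 4
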