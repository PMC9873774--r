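# Demonstration end-to-end run: small population, short EEG segments and
# a reduced bootstrap so the whole pipeline completes in well under a
# minute on one CPU.
seed: 42
output_dir: blinkdt-demo
population:
  n_participants: 24
eeg:
  fs: 125
  duration: 60
  noise_sd: 15
  write_eeg: false
mediation:
  n_boot: 1000
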