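# 20-cell smoke-test configuration: a miniature two-condition experiment
# (unablated control vs ablation of 5 cells). Units: um, minutes.
seed: 1
out_dir: orgrepair-example
experiment:
  n_organoids: 2
  conditions:
    control: 0
    ablate5: 5
synth:
  n_cells: 20
  radius_um: 25
  n_frames: 5
  labels:
    baseline_rate: 0.2
detect:
  z_window_um: 6
track:
  max_link_um: 15
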