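# Model-comparison study: eight temporal combinations, drift-diffusion
# reference parameters, default trial settings and amplitude grid.
stimuli: table2
trial:
  T: 500.0
  dt: 0.01
  N: 200
  seed: 1
ddm:
  alpha1: 0.5
  tau1: 0.1
  tau2: 50.0
  alpha2: 0.02
  sigma: 0.05
  l: 1
  tau_s: 1.5
grid:
  from: 0.0
  to: 2.0
  by: 0.01
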