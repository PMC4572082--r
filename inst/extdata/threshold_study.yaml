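# Threshold study: the four experimental combinations and the matched
# parameter sets whose model thresholds track the human-subject data.
stimuli: table1
trial:
  T: 500.0
  dt: 0.01
  N: 200
  seed: 1
ddm:
  alpha1: 0.06
  tau1: 0.4
  tau2: 50.0
  alpha2: 0.031
  sigma: 0.09
  l: 8
  tau_s: 1.5
hm:
  alpha1: 0.06
  tau1: 0.4
  tau2: 50.0
  alphaL: 0.006
  sigmaL: 0.001
  lambdaL: 0.01
  tau_s: 1.5
grid:
  from: 0.0
  to: 2.0
  by: 0.01
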