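# Reference parameterization of the foraging-under-predation model.
# All rates are per second; dt in seconds.
model:
  gamma_AP: 0.1          # predator arrival rate
  gamma_PA: 0.1          # predator departure rate
  gamma_GB: 0.01         # habitat good -> bad rate
  gamma_BG: 0.01         # habitat bad -> good rate
  lambda_oi_plus: 0.5    # indirect cue rate, predator present
  lambda_oi_minus: 0.1   # indirect cue rate, predator absent
  lambda_od_plus: 0.9    # direct cue rate (assess only), predator present
  lambda_od_minus: 0.1   # direct cue rate, predator absent
  rho_rG: 0.8            # rich-patch encounter rate, good habitat
  rho_pG: 0.2            # poor-patch encounter rate, good habitat
  rho_rB: 0.2            # rich-patch encounter rate, bad habitat
  rho_pB: 0.8            # poor-patch encounter rate, bad habitat
  r_feed_rich: 2.0
  r_feed_poor: 1.0
  r_rest: 0.0
  r_transit: -0.1
  r_assess: -0.1
  r_freeze: -0.1
  r_escape: -1.0
  r_pred: -100.0         # one-off capture penalty (not a rate)
  delta_by_action:       # detection rates while exposed
    feed: 0.05
    assess: 0.02
    freeze: 0.01
    transit: 0.05
    escape: 0.05
    rest: 0.0
  c_d: 0.0               # decision cost per deliberation
  alpha: 0.1             # exponential discount rate
  dt: 1.0
  d_beta: 0.01           # belief-grid resolution
  tau_set: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
  escape_effective: true
simple:
  p_arrive: 0.01
  p_catch: 0.1
  r_feed: 1.0
  r_catch: -100.0
  c_d: 0.0
  tau_set: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
  d_beta: 0.01
  lambda_oi_plus: 0.5
  lambda_oi_minus: 0.1
  lambda_od_plus: 0.9
  lambda_od_minus: 0.1
solver:
  tol: 1.0e-6
  max_iter: 10000
  grid_mode: bilinear
  interruptible: false
protocol:             # scripted predator schedule; habitat runs free
  - duration: 120.0
    predator: absent
  - duration: 120.0
    predator: present
  - duration: 120.0
    predator: absent
n_trials: 1000
seed: 1
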