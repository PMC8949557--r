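# eatdry default run configuration.
# Every value names its source: "dryer characteristics" and "test
# parameters" refer to the reference dryer's published tables; "design
# choice" values are documented in the methods vignette.
geometry:
  Vg1: 92.382      # dryer characteristics: upper drying section volume, L
  Vg2h1: 107.971   # dryer characteristics: middle drying + tempering volume, L
  Vg3h2: 107.971   # dryer characteristics: lower drying + tempering volume, L
  Vl: 92.382       # dryer characteristics: cooling section volume, L
  Vpp: 69.027      # dryer characteristics: discharge section volume, L
  Vp: 8.0          # dryer characteristics: volume per discharge-wheel rotation, L
equilibrium:
  A: 4.218         # CAE corn desorption constant (published fit)
  B: -32.013       # CAE corn desorption constant (published fit)
  C: -0.0274       # CAE corn desorption constant (published fit)
  form: cae-log-ratio  # design choice: default Te model form (registry)
kinetics:
  a: 0.02          # design choice: synthetic Weibull anchor offset
  b: 0.98          # design choice: synthetic Weibull anchor amplitude
  "N": 1.1         # design choice: synthetic Weibull anchor shape ("N" quoted: bare N is YAML for false)
  k_ref: null      # design choice: calibrated so window selection gives AT0
  T_ref: 100.0     # design choice: map reference hot-air temperature, C
  RH_ref: 0.10     # design choice: map reference hot-air RH, fraction
  V_ref: 0.6      # design choice: map reference air velocity, m/s
  W_ref: 25.5      # test parameters: mean inlet moisture, % w.b.
  alpha_T: 0.010   # design choice: d log k / dT, per C (k rises with T)
  beta_RH: -0.25   # design choice: d log k / dRH
  beta_V: 0.05     # design choice: d log k / dV
  beta_W: -0.005   # design choice: d log k / dW0
  T_range: [40.0, 130.0]  # design choice: map validity range, C
  Me_db: 5.0       # design choice: equilibrium moisture in hot air, % d.b.
  rh_hot: 0.10     # design choice: hot-air RH in drying sections, fraction
  V_air: 0.6       # design choice: hot-air velocity, m/s
sim:
  dt_min: 0.1      # design choice: integration step, min
  tau_g_min: 15.0  # design choice: grain temperature lag constant, min
  gamma: 0.5       # design choice: tempering ratio (tempering/drying time)
  rh_pickup: 0.30  # design choice: exhaust RH rise over ambient, fraction
  ambient_T: 22.0  # test parameters: ambient temperature range midpoint, C
  ambient_RH: 0.335  # test parameters: ambient RH range midpoint, fraction
controller:
  target_wb: 14.5  # test parameters: drying target moisture, % w.b.
  delta1: 0.5      # test parameters: moisture control accuracy band, % w.b.
  delta2: 1.0      # design choice: coarse threshold, 2 x delta1
  epsilon: 0.05    # design choice: dead band on predicted deviation, % w.b.
  W: 30            # design choice: prediction window, discharges
  W_fit: null      # design choice: GA refit window; null = one bed turnover
  H: null          # design choice: horizon = one bed turnover of discharges
  cooldown: 15     # design choice: events between GA adjustments (fine regime)
  warmup: null     # design choice: events before first adjustment; null = one turnover
  tx0: null        # design choice: cold-start interval from the EAT model
  tx_min: 0.5      # design choice: lower bound on discharge interval, min
  tx_max: 30.0     # design choice: upper bound on discharge interval, min
  tx_rate_limit: 0.2   # design choice: max relative tx change per event
  at_gain: 0.25        # design choice: damped area updates (fine regime)
  temp_filter: 1.0     # design choice: EMA weight on zone temps (1 = off)
  at_rate_limit: 0.04  # design choice: max relative AT_set change per adjustment
  k_perturb: 0.9   # design choice: controller anchor k = truth k x 0.9
  inlet_sensor_sd: 0.2  # design choice: inlet moisture measurement error, % w.b.
  gains:
    kH: 0.02       # design choice: window width coefficient
    kS: 0.0        # design choice: window area coefficient (off by default)
    kI: 0.1        # design choice: aspect-ratio (slope) coefficient
    trim: 0.005    # design choice: min of tx trimmed per unit u(k)
  ga:
    pop: 40        # design choice: GA population
    generations: 50  # design choice: GA generations
    pc: 0.9        # design choice: crossover probability
    pm: 0.1        # design choice: mutation probability
    bound: [0.3, 0.1, 0.45, 0.1]  # design choice: per-gene correction bounds (da, db, dk, dN)
    w1: 1.0        # design choice: objective weight on sum |e|
    w2: 0.01       # design choice: objective weight on sum u^2
    w3: 0.1        # design choice: objective weight on rise time
calibration:
  AT0: 12000.0     # test parameters: initial equivalent accumulated temperature, C*min
  setpoints: [110.0, 100.0, 110.0]  # test parameters: continuous-run hot air, C
  inlet_wb: 25.5   # test parameters: inlet moisture range midpoint, % w.b.
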