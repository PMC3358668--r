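# Verify that Brownian motion crosses the unit barrier within one time unit
# with probability at least 10% (true value: 2 * (1 - pnorm(1)) ~ 0.317).
model:
  preset: brownian_barrier
  params:
    a: 1.0
    horizon: 1.0
formula: "F[1](x > 1)"
test:
  theta0: 0.1
  prior: [1.0, 1.0]
  bayes_threshold: 100
  eta: 1.0
  max_samples: 5000
grid:
  t_end: 1.0
  dt: 0.02
perturbation:
  mode: "off"   # quoted: bare `off` is a YAML boolean
  theta_max: 0.0
seed: 11
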