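# example run configuration
seed: 1
geometry:
  theta0_deg: 64
  thetak_deg: 13.7
  L_um: 11.1
  hk_um: 5.0
  xk_um: 5.05
architecture:
  n_k: 17
  n_b: 14
  kappa0_pN_um2: 30
solver:
  n_steps: 50
  tol_pos: 1.0e-3
  tol_ang: 1.0e-3
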