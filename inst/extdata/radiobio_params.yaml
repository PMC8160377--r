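# Radiobiological model parameters, keyed by tissue.
# tumour: LQ-Poisson TCP; urethra: LKB (endpoint urethral stricture);
# bladder/rectum: relative seriality (D50 on the EQD2 scale).
tumour:
  model: lq_poisson
  rho_cl: 2.8e8        # clonogen density, cells/cm^3
  alpha: 0.12050       # 1/Gy, calibrated to 70% TCP at 60 Gy / 3 Gy
  alpha_beta: 1.6      # Gy
urethra:
  model: lkb
  d50: 116.7           # Gy
  m: 0.23
  "n": 0.3
  alpha_beta: 5.0      # Gy, for EQD2 conversion
bladder:
  model: relative_seriality
  d50: 80.0            # Gy as EQD2
  gamma: 2.59
  s: 1.3
  alpha_beta: 3.0
rectum:
  model: relative_seriality
  d50: 80.0            # Gy as EQD2
  gamma: 1.79
  s: 0.75
  alpha_beta: 3.0
weights:               # w_j, equal clinical importance
  urethra: 1.0
  bladder: 1.0
  rectum: 1.0
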