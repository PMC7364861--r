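{
  "comment": "Reference parameter set. Hormone rates per minute, mass and slow-process rates per day.",
  "w1": 0.17,
  "w2": 0.035,
  "w3": 0.0086,
  "wC": 0.099,
  "wA": 0.049,
  "K_GR": 4,
  "n": 3,
  "wCRHE": 0.016,
  "W": 30,
  "D": 20,
  "wR": 0.023104906018664842,
  "wCR": 0.023104906018664842,
  "lam": 1
}
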