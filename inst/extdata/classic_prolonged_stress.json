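{
  "variant": "classic",
  "protocol": { "type": "step", "u": 4, "start": 0, "end": 90, "baseline": 1 },
  "t_start": 0,
  "t_end": 120,
  "solver": { "rtol": 1e-8, "atol": 1e-10, "hmax": 10, "grid_hours": 1 }
}
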