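{
  "grid": {"shape": [120, 120], "spacing": [2, 2]},
  "body": {"center": [0, 0], "semiaxes": [85, 95]},
  "ctv": {"center": [0, -30], "radius": 20},
  "inserts": [
    {"shape": "disc", "center": [0, 25], "size": [15], "sp": 0}
  ],
  "background_sp": 1.0
}
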