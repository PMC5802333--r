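{
  "grid": {"shape": [140, 200], "spacing": [2, 2]},
  "body": {"center": [0, 0], "semiaxes": [180, 130]},
  "ctv": {"center": [0, 0], "radius": 25},
  "inserts": [
    {"shape": "disc", "center": [-120, 0], "size": [22], "sp": 1.622},
    {"shape": "disc", "center": [120, 0], "size": [22], "sp": 1.622}
  ],
  "background_sp": 1.0
}
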