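{
  "seed": 421,
  "n_animals": 3,
  "stats": {
    "B_perm": 500,
    "B_boot": 200
  }
}
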