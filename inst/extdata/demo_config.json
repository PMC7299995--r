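{
  "seed": 7,
  "simulate": { "condition": "control", "pixel_size_nm": 100 },
  "transects": ["2,44:86,44"],
  "ratio_element": "Sr"
}
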