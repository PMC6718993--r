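{
  "conventional": 0,
  "cloth_coveralls": 0,
  "sms_coveralls": 0.5,
  "polyolefin_coveralls": 1,
  "double_layer": 3,
  "vapor_barrier": 11
}
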