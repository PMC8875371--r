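{
  "conduction": { "rr": 900, "lbbb": false, "myocardial_delay": 1 },
  "engine": { "dt": 0.5, "cycles": 15, "transient": 5 }
}
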