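{
  "conduction": { "rr": 900, "lbbb": true, "myocardial_delay": 29 },
  "circulation": { "links": { "sys_art_sys_ven": 2.4 } },
  "mechanics": {
    "segments": {
      "name": ["basal_anteroseptal", "basal_inferoseptal", "mid_anteroseptal",
               "mid_inferoseptal", "apical_septal",
               "basal_inferolateral", "basal_anterolateral",
               "mid_inferolateral", "mid_anterolateral", "apical_lateral"],
      "k_act": [0.5, 0.5, 0.5, 0.5, 0.5, 0.78, 0.78, 0.78, 0.78, 0.78]
    }
  }
}
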