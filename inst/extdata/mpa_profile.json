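{
  "name": "mycophenolic acid",
  "molecular_weight": 320.34,
  "prodrug_molecular_weight": 433.5,
  "pka_values": [4.58, 8.045],
  "log_dow_by_ph": {
    "5": 2.28,
    "7": 0.48,
    "9": -1.54
  },
  "water_solubility_by_ph": {
    "5": 45,
    "7": 710
  },
  "bcf_by_ph": {
    "5": 161,
    "6": 23.2,
    "7": 2.49,
    "8": 1,
    "9": 1,
    "10": 1
  },
  "vapor_pressure": 4.27e-07,
  "hydrolysis_loss_by_ph": {
    "5": 46.15,
    "7": 29.03,
    "9": 36.67
  },
  "photolysis_rate_by_condition": {
    "ph5_winter": 0.0017,
    "ph5_summer": 0.0059,
    "ph7_winter": 0.0049,
    "ph7_summer": 0.018,
    "ph9_winter": 0.0087,
    "ph9_summer": 0.031,
    "uvc": 0.0284,
    "solar_box": 0.004
  },
  "cmr": true
}
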