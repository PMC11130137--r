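{
  "n_nests": 51,
  "prop_old": 0.6,
  "overdispersion": 0.45,
  "spatial_sd": 0.5,
  "spatial_range": 120,
  "groups": [
    {
      "id": "spider_P",
      "log_base": -0.223,
      "beta_age": 2.932,
      "beta_moisture": 0.0
    },
    {
      "id": "rove_beetle_P",
      "log_base": -0.511,
      "beta_age": 2.909,
      "beta_moisture": 0.0
    },
    {
      "id": "rove_beetle_SP1",
      "log_base": -0.799,
      "beta_age": 2.996,
      "beta_moisture": 0.0
    },
    {
      "id": "rove_beetle_SP2",
      "log_base": 0.095,
      "beta_age": 2.996,
      "beta_moisture": 0.0
    },
    {
      "id": "rove_beetle_S",
      "log_base": 0.693,
      "beta_age": 3.314,
      "beta_moisture": 0.0
    },
    {
      "id": "beetle_D",
      "log_base": 0.405,
      "beta_age": 2.996,
      "beta_moisture": 0.2
    },
    {
      "id": "beetle_B",
      "log_base": -0.916,
      "beta_age": 2.996,
      "beta_moisture": 0.0
    },
    {
      "id": "springtail_D",
      "log_base": 1.792,
      "beta_age": 3.912,
      "beta_moisture": 0.2
    },
    {
      "id": "isopod_D",
      "log_base": 1.03,
      "beta_age": 2.659,
      "beta_moisture": 0.2
    },
    {
      "id": "fac_armoured_D",
      "log_base": 3.401,
      "beta_age": -0.069,
      "beta_moisture": 0.2
    },
    {
      "id": "fac_pred_P1",
      "log_base": -0.693,
      "beta_age": 0.0,
      "beta_moisture": 0.0
    },
    {
      "id": "fac_pred_P2",
      "log_base": -1.204,
      "beta_age": 0.0,
      "beta_moisture": 0.0
    },
    {
      "id": "fac_prey_D",
      "log_base": 5.438,
      "beta_age": -0.427,
      "beta_moisture": 0.2
    },
    {
      "id": "fac_rove_beetle_S",
      "log_base": 2.773,
      "beta_age": 0.0,
      "beta_moisture": 0.0
    },
    {
      "id": "fac_mite_D",
      "log_base": 4.787,
      "beta_age": -0.087,
      "beta_moisture": 0.2
    },
    {
      "id": "fac_mite_P",
      "log_base": 4.127,
      "beta_age": -0.831,
      "beta_moisture": 0.0
    }
  ]
}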