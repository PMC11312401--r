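[
  {"label": "pH7.0", "group": "pH", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 38, "interval_mean": 234,
   "interval_sigma_log": 0.45, "amplitude": 0.57, "target_cbf": 3.4,
   "n_cilia": 4},
  {"label": "pH7.2", "group": "pH", "mode": "rate_matched",
   "t_eff": 90, "t_rec": 38, "interval_mean": 212,
   "interval_sigma_log": 0.45, "amplitude": 0.81, "target_cbf": 5.0,
   "n_cilia": 4},
  {"label": "pH7.4", "group": "pH", "mode": "rate_matched",
   "t_eff": 44, "t_rec": 38, "interval_mean": 120,
   "interval_sigma_log": 0.45, "amplitude": 0.98, "target_cbf": 8.8,
   "n_cilia": 11, "reference": true},
  {"label": "pH7.6", "group": "pH", "mode": "rate_matched",
   "t_eff": 37, "t_rec": 38, "interval_mean": 53,
   "interval_sigma_log": 0.45, "amplitude": 1.31, "target_cbf": 11.5,
   "n_cilia": 6},
  {"label": "pH7.8", "group": "pH", "mode": "rate_matched",
   "t_eff": 37, "t_rec": 38, "interval_mean": 44,
   "interval_sigma_log": 0.45, "amplitude": 1.31, "target_cbf": 13.7,
   "n_cilia": 6},
  {"label": "pH8.0", "group": "pH", "mode": "rate_matched",
   "t_eff": 37, "t_rec": 38, "interval_mean": 31,
   "interval_sigma_log": 0.45, "amplitude": 1.45, "target_cbf": 15.4,
   "n_cilia": 4},

  {"label": "rep_pH7.0", "group": "representative", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 38, "interval_mean": 234,
   "interval_sigma_log": 0.45, "amplitude": 0.6, "target_cbf": 3.0,
   "n_cilia": 1},
  {"label": "rep_pH7.4", "group": "representative", "mode": "rate_matched",
   "t_eff": 44, "t_rec": 38, "interval_mean": 120,
   "interval_sigma_log": 0.45, "amplitude": 1.0, "target_cbf": 7.0,
   "n_cilia": 1},
  {"label": "rep_pH8.0", "group": "representative", "mode": "rate_matched",
   "t_eff": 37, "t_rec": 38, "interval_mean": 31,
   "interval_sigma_log": 0.45, "amplitude": 1.5, "target_cbf": 12.0,
   "n_cilia": 1},

  {"label": "ATP0.5mM", "group": "ATP", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 40, "interval_mean": 1273,
   "interval_sigma_log": 0.45, "amplitude": 0.30, "target_cbf": 0.69,
   "n_cilia": 4},
  {"label": "ATP2.5mM", "group": "ATP", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 40, "interval_mean": 518,
   "interval_sigma_log": 0.45, "amplitude": 0.44, "target_cbf": 1.44,
   "n_cilia": 5},
  {"label": "ATP7.5mM", "group": "ATP", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 40, "interval_mean": 866,
   "interval_sigma_log": 0.45, "amplitude": 0.36, "target_cbf": 0.96,
   "n_cilia": 5},
  {"label": "ATP10mM", "group": "ATP", "mode": "rate_matched",
   "t_eff": 136, "t_rec": 40, "interval_mean": 2324,
   "interval_sigma_log": 0.45, "amplitude": 0.20, "target_cbf": 0.40,
   "n_cilia": 4},

  {"label": "unstimulated", "group": "null", "mode": "component_matched",
   "t_eff": 40, "t_rec": 40, "interval_mean": 0,
   "interval_sigma_log": 0, "amplitude": 0,
   "fluct_sd": 0.04, "fluct_tau": 300, "n_cilia": 5},
  {"label": "ATPgS", "group": "null", "mode": "component_matched",
   "t_eff": 40, "t_rec": 40, "interval_mean": 0,
   "interval_sigma_log": 0, "amplitude": 0,
   "fluct_sd": 0.04, "fluct_tau": 300, "n_cilia": 5},
  {"label": "PKI_pre", "group": "null", "mode": "component_matched",
   "t_eff": 40, "t_rec": 40, "interval_mean": 0,
   "interval_sigma_log": 0, "amplitude": 0,
   "fluct_sd": 0.04, "fluct_tau": 300, "n_cilia": 5}
]
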