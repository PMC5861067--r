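{
  "feeding_canal": {
    "length_m": 0.00156,
    "diameter_m": 2.5e-05
  },
  "pharynx": {
    "length_m": 0.0002,
    "diameter_m": 2.5e-05
  },
  "esophagus": {
    "length_m": 0.0001,
    "diameter_m": 5e-05
  },
  "valve": {
    "constricted_length_m": 2e-05,
    "constricted_diameter_m": 5e-06,
    "esophageal_backflow_factor": 1000000
  },
  "cibarial": {
    "length_m": 0.000232,
    "h_min_m": 3.8e-05,
    "h_max_continuous_m": 5e-05,
    "h_max_burst_m": 6.3e-05
  },
  "pharyngeal": {
    "length_m": 0.000326,
    "h_min_m": 4.4e-05,
    "h_max_continuous_m": 5e-05,
    "h_max_burst_m": 0.000256
  },
  "fluid": {
    "density_kg_m3": 1100,
    "viscosity_pa_s": 0.003,
    "surface_tension_n_m": 0.077
  },
  "boundaries": {
    "p_food_pa": 0,
    "p_gut_pa": 0,
    "p_hemo_pa": 0,
    "p_atm_pa": 0,
    "dp_gut_pa": 0
  },
  "timing": {
    "t_c_s": 0.2335,
    "tau_cp_c_s": 0,
    "tau_pp_c_s": 0.0835,
    "t_b_s": 0.703,
    "t_s_cp_s": 0.0004,
    "t_e_cp_s": 0.662,
    "t_s_pp_s": 0.153,
    "t_e_pp_s": 0.646
  }
}
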