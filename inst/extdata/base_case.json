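{
  "model": {
    "start_age": 70,
    "cohort_size": 1000,
    "horizon_cycles": 432,
    "cycle_length_months": 1,
    "discount_rate_annual": 0.035,
    "deferred_fraction": 0.20,
    "ae_window_cycles": 3
  },
  "parameters": {
    "p_metastatic_in_progression": {"family": "beta", "mean": 0.4, "se": 0.08},
    "p_deferred_to_adt": {"family": "beta", "mean": 0.014, "se": 0.005},
    "p_adt_to_progression": {"family": "beta", "mean": 0.016, "se": 0.004},
    "rr_progression_post_sc": {"family": "lognormal", "mean": 1.5, "se": 1.38},
    "spline_gamma0": {"family": "normal", "mean": -4.58, "se": 0.408},
    "spline_gamma1": {"family": "normal", "mean": 1.01, "se": 0.096},
    "spline_gamma2": {"family": "normal", "mean": 0.303, "se": 0.068},
    "p_fistula": {"family": "beta", "mean": 0.05, "se": 0.010},
    "p_incontinence": {"family": "beta", "mean": 0.12, "se": 0.024},
    "p_retention": {"family": "beta", "mean": 0.07, "se": 0.014},
    "p_luts": {"family": "beta", "mean": 0.14, "se": 0.028},
    "p_perineal_pain": {"family": "beta", "mean": 0.04, "se": 0.008},
    "p_haematuria": {"family": "beta", "mean": 0.05, "se": 0.01},
    "p_stricture": {"family": "beta", "mean": 0.10, "se": 0.02},
    "p_hot_flush": {"family": "beta", "mean": 0.10, "se": 0.02},
    "cost_fistula": {"family": "gamma", "mean": 4039, "se": 808},
    "cost_incontinence": {"family": "gamma", "mean": 2170, "se": 434},
    "cost_retention": {"family": "gamma", "mean": 3963, "se": 793},
    "cost_haematuria": {"family": "gamma", "mean": 2445, "se": 489},
    "cost_stricture": {"family": "gamma", "mean": 3836, "se": 767},
    "cost_luts": {"family": "fixed", "mean": 10.47},
    "cost_perineal_pain": {"family": "fixed", "mean": 5.16},
    "cost_hot_flush_per_cycle": {"family": "fixed", "mean": 5.54},
    "surgeon_hours": {"family": "gamma", "mean": 2.5, "se": 0.25},
    "theatre_hours": {"family": "gamma", "mean": 2.0, "se": 0.2},
    "overnight_stays": {"family": "gamma", "mean": 2.0, "se": 0.2},
    "catheter_hours": {"family": "gamma", "mean": 0.6666666666666666, "se": 0.066},
    "delivery_hours": {"family": "gamma", "mean": 0.3333333333333333, "se": 0.066},
    "u_dfs": {"family": "beta", "mean": 0.774, "se": 0.02},
    "u_progression_metastatic": {"family": "beta", "mean": 0.42, "se": 0.06},
    "u_progression_nonmetastatic": {"family": "beta", "mean": 0.68, "se": 0.022},
    "du_fistula": {"family": "beta", "mean": 0.15, "se": 0.03}
  },
  "unit_costs": {
    "ultrasound": 47.84,
    "theatre_per_hour": 1125.0,
    "consultant_per_hour": 142.0,
    "additional_theatre": 260.61,
    "needle_kit": 5052.17,
    "overnight_stay": 237.34,
    "nurse_per_hour": 53.0,
    "sc_medication": 33.75,
    "goserelin": 65.0,
    "bicalutamide": 5.54,
    "abiraterone_per_cycle": 2930.0,
    "leuprorelin": 75.24,
    "flutamide": 25.37
  },
  "spline_knots_log_months": [0.0, 3.1780538303479458, 4.787491742782046],
  "flags": {
    "metastatic_cost_same_as_nonmetastatic": false,
    "subtract_pc_from_background": false,
    "half_cycle_correction": false,
    "ae_costs_at_cycle0": false
  }
}
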