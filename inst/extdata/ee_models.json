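{
  "schema": "ankleEE/model-coefficients",
  "version": "1.0",
  "models": [
    {"name": "freedson_vm3", "model": "freedson", "group": null,
     "output_units": "kcal/min",
     "intercept": -5.500229, "b_vm": 0.001064, "b_bw": 0.087512,
     "b_hrr": null, "r_squared": null, "see": null},
    {"name": "modelA_SG", "model": "modelA", "group": "SG",
     "output_units": "kcal/kg/min",
     "intercept": 0.007852, "b_vm": 0.000006, "b_bw": -0.000292,
     "b_hrr": null, "r_squared": 0.947, "see": 0.011},
    {"name": "modelA_EHG", "model": "modelA", "group": "EHG",
     "output_units": "kcal/kg/min",
     "intercept": 0.020757, "b_vm": 0.000006, "b_bw": -0.000419,
     "b_hrr": null, "r_squared": 0.898, "see": 0.015},
    {"name": "modelA_NEG", "model": "modelA", "group": "NEG",
     "output_units": "kcal/kg/min",
     "intercept": -0.005442, "b_vm": 0.000007, "b_bw": -0.000168,
     "b_hrr": null, "r_squared": 0.870, "see": 0.019},
    {"name": "modelA_EG", "model": "modelA", "group": "EG",
     "output_units": "kcal/kg/min",
     "intercept": 0.007280, "b_vm": 0.000006, "b_bw": -0.000170,
     "b_hrr": null, "r_squared": 0.867, "see": 0.018},
    {"name": "modelB_SG", "model": "modelB", "group": "SG",
     "output_units": "kcal/kg/min",
     "intercept": 0.012550, "b_vm": 0.000005, "b_bw": -0.000271,
     "b_hrr": 0.000284, "r_squared": 0.951, "see": 0.010},
    {"name": "modelB_EHG", "model": "modelB", "group": "EHG",
     "output_units": "kcal/kg/min",
     "intercept": 0.031277, "b_vm": 0.000004, "b_bw": -0.000417,
     "b_hrr": 0.000478, "r_squared": 0.894, "see": 0.016},
    {"name": "modelB_NEG", "model": "modelB", "group": "NEG",
     "output_units": "kcal/kg/min",
     "intercept": 0.021134, "b_vm": 0.000005, "b_bw": -0.000342,
     "b_hrr": 0.000542, "r_squared": 0.880, "see": 0.018},
    {"name": "modelB_EG", "model": "modelB", "group": "EG",
     "output_units": "kcal/kg/min",
     "intercept": 0.014313, "b_vm": 0.000005, "b_bw": -0.000200,
     "b_hrr": 0.000304, "r_squared": 0.870, "see": 0.018}
  ]
}
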