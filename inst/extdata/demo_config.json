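{
  "seed": 20210719,
  "out_dir": "golgiph_demo",
  "electro": {
    "ph_lumen": 6.0, "ph_cytosol": 7.0,
    "k_lumen": 107, "k_cytosol": 140,
    "cl_cytosol": 4, "temperature": 310.15
  },
  "phquant": {"n_cells": 1000, "calibration_cv": 0.02},
  "kinetics": {"preset": "cos7_control", "bath": "cl_hco3",
               "t_end": 30, "cma_time": 16},
  "lectin": {
    "alpha": 0.05,
    "fold_map_pair1": {"ACA": 2.0, "RCA120": 0.5, "PNA": 1.8},
    "fold_map_pair2": {"ACA": 1.8, "RCA120": 0.55, "WGA": 1.6}
  }
}
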