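{
  "description": "Control COS-7 calibration (endogenous AE2a level).",
  "compartment": {"volume_fL": 5, "surface_area_um2": 100, "beta": 20,
                  "pH": 6.5, "cl": 60, "hco3": 3, "co2": 3},
  "params": {"pump_vmax": 20, "pump_Km_ATP": 0.3, "pump_pH_floor": 4.8,
             "pump_bp_ref": 7.2, "passive_H_permeability": 600,
             "cl_channel_rate": 2, "ae2_density": 1.0,
             "ae2_turnover": 31, "ae2_Km_hco3": 5, "ae2_Km_cl": 10,
             "ae2_pH_gate_midpoint": 5.0, "ae2_pH_gate_steepness": 4,
             "co2_permeability": 2.5, "buffer_pKa": 6.4,
             "buffer_forward_rate": 100000},
  "baths": {
    "no_anions": {"pH": 7.2, "cl": 0, "hco3": 0, "co2": 0},
    "cl_only":   {"pH": 7.2, "cl": 120, "hco3": 2, "co2": 0.32},
    "cl_hco3":   {"pH": 7.2, "cl": 120, "hco3": 20, "co2": 3.17}
  },
  "cytosol": {"pH": 7.0, "atp": 3, "cl": 40, "hco3": 12, "co2": 3.01}
}
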