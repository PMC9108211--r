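{
  "geometry": {
    "box_dims": [0.6, 0.6, 0.3],
    "has_tbar": true,
    "roof_diameter": 0.14,
    "roof_thickness": 0.01,
    "leg_height": 0.04,
    "leg_diameter": 0.03,
    "channels_clustered": true,
    "channel_zone_outer_diameter": 0.07,
    "n_channels": 6,
    ".az_class": "az_geometry"
  },
  "h": 0.01,
  "kinetics": {
    "D_Ca": 200,
    "D_B": 30,
    "k_on": 44,
    "k_off": 36,
    "B_total": 40,
    "Ca_V0": 0.05,
    "Ca_e": 1500,
    "K_D": 0.818181818181818,
    "B_V0": 37.696335078534,
    ".az_class": "az_kinetics"
  },
  "channel": {
    "p_x": 0.1,
    "a": 2,
    "b": 1,
    "gates": {
      "m": {
        "V_half": -21,
        "z_g": 3.4,
        "gamma": 0.8,
        "alpha0": 800,
        "tau0": 0.002,
        ".az_class": "az_gate"
      },
      "h": {
        "V_half": -40,
        "z_g": -2,
        "gamma": 0.5,
        "alpha0": 40,
        "tau0": 0.075,
        ".az_class": "az_gate"
      }
    },
    ".az_class": "az_channel"
  },
  "pumps": {
    "I_p": 8e-24,
    "H_p": 0.06,
    "n_p": 2,
    "I_x": 2.5e-21,
    "H_x": 1.8,
    "n_x": 1,
    "n_x_den": 1,
    "rho_pmca": 75000,
    "rho_ncx": 2500,
    "leak_flux": 0,
    ".az_class": "az_pumps"
  },
  "train": {
    "frequency": 40,
    "duration": 0.05,
    "V_rest": -70,
    "V_peak": 20,
    "tau_rise": 0.001,
    "tau_decay": 0.0025,
    "support": 0.008,
    "norm": 0.318109142875378,
    "w_end": 0.0404267413504637,
    "waveform": null,
    ".az_class": "az_train"
  },
  "solver": {
    "dt_spike": 2e-06,
    "dt_rest": 2e-05,
    "spike_window": 0.006,
    "method": "adi",
    "wall_bc": "dirichlet",
    "reaction_mode": "exact",
    "lin_tol": 1e-10,
    "max_halvings": 20,
    "record_every": 1,
    ".az_class": "az_solver"
  },
  "probes": {
    "R": [0.02, 0.03, 0.04, 0.05],
    "H": [0.01, 0.02, 0.03, 0.04],
    "n_phi_max": 64
  },
  "t_end": 0.05,
  "V_rest": -70,
  "constants": {
    "F_faraday": 96480,
    "R_gas": 8.314,
    "T_kelvin": 300,
    "z": 2
  },
  "rho_vgcc_override": null,
  "snapshot_times": null,
  "label": "tbar_clustered",
  ".az_class": "az_config"
}
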