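{
  "cell_type": "rat_neostriatal",
  "species": {
    "Na": {
      "name": "Na",
      "z": 1,
      "D": 1.33e-09,
      "a": 3.58e-10,
      "c_i0": 12,
      "c_o0": 145
    },
    "K": {
      "name": "K",
      "z": 1,
      "D": 1.96e-09,
      "a": 3.31e-10,
      "c_i0": 139,
      "c_o0": 4
    },
    "Ca": {
      "name": "Ca",
      "z": 2,
      "D": 7.9e-10,
      "a": 4.12e-10,
      "c_i0": 0.0001,
      "c_o0": 2
    },
    "Cl": {
      "name": "Cl",
      "z": -1,
      "D": 2.03e-09,
      "a": 3.32e-10,
      "c_i0": 10,
      "c_o0": 140
    }
  },
  "geometry": {
    "R_cell": 3.3e-06,
    "R_domain": 9.9e-06,
    "d_mem": 5e-09,
    "N_theta": 13,
    "N_r_in": 15,
    "N_r_out": 15
  },
  "electrical": {
    "C_m": 0.01,
    "g1": 2,
    "V_rest": -0.07,
    "sigma_i": 0.455,
    "sigma_o": 1.2,
    "T": 310
  },
  "pore": {
    "alpha": 1000000000,
    "V_ep": 0.258,
    "N0": 1500000000,
    "r_star": 5.1e-10,
    "r_m": 8e-10,
    "q_exp": 2,
    "D_p": 5e-14,
    "F_max": 7e-10,
    "r_h": 9.7e-10,
    "r_t": 3.1e-10,
    "beta": 1.4e-19,
    "gamma": 1.8e-11,
    "sigma_prime": 0.02,
    "sigma_0": 1e-06
  },
  "atpase": {
    "k1p": 1050,
    "k2p": 481,
    "k3p": 2000,
    "k4p": 320,
    "k1m": 172.1,
    "k2m": 40,
    "k3m": 172,
    "k4m": 40,
    "kd_Nai0": 5,
    "kd_Nao0": 70,
    "kd_Ki0": 16,
    "kd_Ko0": 1.2,
    "kd_MgATP": 0.14,
    "d_Nai": -0.14,
    "d_Nao": 0.44,
    "d_Ki": -0.14,
    "d_Ko": 0.23,
    "c_MgATP": 6.8,
    "c_MgADP": 0.04,
    "c_P": 1,
    "pH": 7.2,
    "F_c": 1e-12
  },
  "options": {
    "include_pump_current_in_vm": false,
    "extracellular_bath": "finite",
    "negative_conc": "substep",
    "cohort_cap": 64,
    "spawn_min": 0.001,
    "merge_tol": 0.001,
    "exp_clamp": 50,
    "vep_ratio_cap": 250
  },
  "constants": {
    "F": 96485.33212,
    "R_u": 8.31446262,
    "k_B": 1.380649e-23,
    "N_A": 6.02214076e+23,
    "q_ele": 1.602176634e-19,
    "Q_ATP": 4.2800119e-20
  }
}
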