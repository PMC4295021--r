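{
  "dgr0_table": {
    "reaction": "CH3COO- + SO4-- -> 2 HCO3- + HS-",
    "pressure_MPa": 27,
    "method": "constant-dCp integration of 25 C standard-state data",
    "dGr0_25C_kJ_mol": -48.13,
    "dHr0_25C_kJ_mol": -0.27,
    "dSr0_25C_J_mol_K": 160.5232,
    "dCpr_J_mol_K": 79.2,
    "source": "SUPCRT-compatible aqueous standard-state compilations (Shock & Helgeson family)"
  },
  "debye_huckel": {
    "model": "extended Debye-Huckel with B-dot term",
    "source": "Helgeson (1969)-style temperature tabulation"
  }
}
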