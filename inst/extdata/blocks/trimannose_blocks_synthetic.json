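{
  "name": "trimannose-lowenergy-synthetic",
  "catalog": "trimannose",
  "synthetic": true,
  "comment": "Low-energy trimannose building blocks. Relative energies (0 K, kJ/mol) are SYNTHETIC stand-ins for externally computed quantum-chemistry values, except the 20.1 kJ/mol outlier which exercises the 10 kJ/mol selection window. Three blocks survive the default selection.",
  "entries": [
    {"id": "A1", "group": "A",
     "directions": {"armA": "fwd", "armB": "fwd"},
     "rel_energy_kjmol": 0.0},
    {"id": "J2", "group": "J",
     "directions": {"armM1": "rev"},
     "rel_energy_kjmol": 1.8},
    {"id": "B1", "group": "B",
     "directions": {"armB": "fwd"},
     "rel_energy_kjmol": 4.6},
    {"id": "G1", "group": "G",
     "directions": {},
     "rel_energy_kjmol": 20.1}
  ]
}
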