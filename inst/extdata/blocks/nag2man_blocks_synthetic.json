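{
  "name": "nag2man-lowenergy-synthetic",
  "catalog": "nag2man-trisaccharide",
  "synthetic": true,
  "comment": "Low-energy Man-b(1,4)-GlcNAc-b(1,4)-GlcNAc building blocks. Relative energies (0 K, kJ/mol) are SYNTHETIC stand-ins for externally computed quantum-chemistry values; two blocks survive the default 10 kJ/mol selection.",
  "entries": [
    {"id": "F1", "group": "F",
     "directions": {"lower": "fwd"},
     "rel_energy_kjmol": 0.0},
    {"id": "R1", "group": "R",
     "directions": {"lowerM": "fwd"},
     "rel_energy_kjmol": 0.2},
    {"id": "C1", "group": "C",
     "directions": {"lower": "fwd"},
     "rel_energy_kjmol": 12.4}
  ]
}
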