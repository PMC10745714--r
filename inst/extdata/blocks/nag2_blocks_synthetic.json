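{
  "name": "nag2-disaccharide-synthetic",
  "catalog": "nag2-disaccharide",
  "synthetic": true,
  "comment": "Chitobiose (GlcNAc-b(1,4)-GlcNAc) building blocks with SYNTHETIC stand-in relative energies; both survive the default 10 kJ/mol selection.",
  "entries": [
    {"id": "D1", "group": "D1", "directions": {}, "rel_energy_kjmol": 0.0},
    {"id": "D2", "group": "D2", "directions": {}, "rel_energy_kjmol": 3.2}
  ]
}
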