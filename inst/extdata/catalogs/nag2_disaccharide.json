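{
  "name": "nag2-disaccharide",
  "molecule": "GlcNAc-b(1,4)-GlcNAc",
  "comment": "Chitobiose building block used by the pentasaccharide block-combination strategies. Rings G' (non-reducing) and G (reducing). Linkage slot 'link'.",
  "topology": {
    "residues": [
      {"tag": "G'", "template": "beta-D-GlcNAc"},
      {"tag": "G", "template": "beta-D-GlcNAc"}
    ],
    "linkages": [
      {"child": "G'", "parent": "G", "parent_pos": 4, "slot": "link"}
    ]
  },
  "vocabulary": [
    {"label": "OH6'", "residue": "G'", "site": "OH6", "role": "site"},
    {"label": "OH3'", "residue": "G'", "site": "OH3", "role": "site"},
    {"label": "NHCO'", "residue": "G'", "site": "NHCO", "role": "site"},
    {"label": "OH1'", "residue": "G'", "site": "OH1", "role": "site"},
    {"label": "OH6", "residue": "G", "site": "OH6", "role": "site"},
    {"label": "OH3", "residue": "G", "site": "OH3", "role": "site"},
    {"label": "NHCO", "residue": "G", "site": "NHCO", "role": "site"},
    {"label": "OH1", "residue": "G", "site": "OH1", "role": "site"},
    {"label": "OG'", "residue": "G'", "site": "RING_O", "role": "oxygen"},
    {"label": "OG", "residue": "G", "site": "RING_O", "role": "oxygen"},
    {"label": "O", "residue": "G", "site": "B4", "role": "oxygen"},
    {"label": "O1", "residue": "G", "site": "OH1", "role": "oxygen"}
  ],
  "groups": [
    {
      "label": "D1",
      "classes": {"link": "trans"},
      "units": [
        {"id": "upper", "region": "upper", "reversible": false,
         "fwd": ["OH6'->OH6->OG"]},
        {"id": "lower", "region": "lower", "reversible": false,
         "fwd": ["NHCO'->OH3->NHCO->O1"]}
      ],
      "expected_count": 1
    },
    {
      "label": "D2",
      "classes": {"link": "cis"},
      "units": [
        {"id": "upper", "region": "upper", "reversible": false,
         "fwd": ["OH6->OH6'->OG'"]},
        {"id": "lower", "region": "lower", "reversible": false,
         "fwd": ["NHCO'->OH3->NHCO->O1"]}
      ],
      "expected_count": 1
    }
  ]
}
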