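{
  "name": "trimannose",
  "molecule": "Man-a(1,3)[Man-a(1,6)]Man",
  "comment": "Building-tree inventory for branched trimannose. Rings: M (central), M' (1->3 arm), M'' (1->6 arm). Linkage slot 'first' is the M'-M bond, 'second' the M-M'' bond. Unprimed group labels live on ring M; O/OM, O'/OM' and OM'' are the ring oxygens of M, M' and M''.",
  "topology": {
    "residues": [
      {"tag": "M", "template": "alpha-D-Man"},
      {"tag": "M'", "template": "alpha-D-Man"},
      {"tag": "M''", "template": "alpha-D-Man"}
    ],
    "linkages": [
      {"child": "M'", "parent": "M", "parent_pos": 3, "slot": "first"},
      {"child": "M''", "parent": "M", "parent_pos": 6, "slot": "second"}
    ]
  },
  "vocabulary": [
    {"label": "OH1", "residue": "M", "site": "OH1", "role": "site"},
    {"label": "OH2", "residue": "M", "site": "OH2", "role": "site"},
    {"label": "OH4", "residue": "M", "site": "OH4", "role": "site"},
    {"label": "OH2'", "residue": "M'", "site": "OH2", "role": "site"},
    {"label": "OH3'", "residue": "M'", "site": "OH3", "role": "site"},
    {"label": "OH4'", "residue": "M'", "site": "OH4", "role": "site"},
    {"label": "OH6'", "residue": "M'", "site": "OH6", "role": "site"},
    {"label": "OH2''", "residue": "M''", "site": "OH2", "role": "site"},
    {"label": "OH3''", "residue": "M''", "site": "OH3", "role": "site"},
    {"label": "OH4''", "residue": "M''", "site": "OH4", "role": "site"},
    {"label": "OH6''", "residue": "M''", "site": "OH6", "role": "site"},
    {"label": "O", "residue": "M", "site": "RING_O", "role": "oxygen"},
    {"label": "OM", "residue": "M", "site": "RING_O", "role": "oxygen"},
    {"label": "O'", "residue": "M'", "site": "RING_O", "role": "oxygen"},
    {"label": "OM'", "residue": "M'", "site": "RING_O", "role": "oxygen"},
    {"label": "OM''", "residue": "M''", "site": "RING_O", "role": "oxygen"},
    {"label": "OB3", "residue": "M", "site": "B3", "role": "oxygen"},
    {"label": "OB6", "residue": "M", "site": "B6", "role": "oxygen"}
  ],
  "groups": [
    {
      "label": "A",
      "classes": {"first": "cis", "second": "cis"},
      "units": [
        {"id": "armA", "reversible": true,
         "fwd": ["OH6''->OH4'->OH3'->OH2'"]},
        {"id": "armB", "reversible": true,
         "fwd": ["OH2''->OH3''->OH4''->OH6'->OH2->O"]},
        {"id": "anchor", "reversible": false,
         "fwd": ["OH4->O'"]}
      ],
      "expected_count": 4
    },
    {
      "label": "B",
      "classes": {"first": "cis", "second": "cis"},
      "units": [
        {"id": "armA", "reversible": false,
         "fwd": ["OH2'->OH3'->OH4'->OH6''->OM''"]},
        {"id": "armB", "reversible": true,
         "fwd": ["OH2''->OH3''->OH4''->OH6'->OH2->O"]},
        {"id": "anchor", "reversible": false,
         "fwd": ["OH4->O'"]}
      ],
      "expected_count": 2
    },
    {
      "label": "C",
      "classes": {"first": "cis", "second": "cis"},
      "units": [
        {"id": "armA", "reversible": true,
         "fwd": ["OH4''->OH4'->OH3'->OH2'"]},
        {"id": "armB", "reversible": true,
         "fwd": ["OH2''->OH3''->OH6'->OH2->OM"]}
      ],
      "expected_count": 4,
      "warn": "inter-ring bond OH4''->OH4' lacks hydroxymethyl flexibility; equilibration during optimization may break it"
    },
    {
      "label": "D",
      "classes": {"first": "cis", "second": "cis"},
      "units": [
        {"id": "armA", "reversible": true,
         "fwd": ["OH4''->OH4'->OH3'->OH2'"]},
        {"id": "armB", "reversible": true,
         "fwd": ["OH2''->OH3''->OH6'->OH2->OM"]}
      ],
      "c6_rotamers": {"M''": "tg"},
      "expected_count": 4,
      "warn": "inter-ring bond OH4''->OH4' lacks hydroxymethyl flexibility; equilibration during optimization may break it"
    },
    {
      "label": "E",
      "classes": {"first": "cis", "second": "trans"},
      "units": [
        {"id": "coop", "reversible": true,
         "fwd": ["OH4''->OH3''->OH2''->OH6'->OH2->OM", "OH4'->OH3'->OH2'"],
         "rev": ["OH2->OH6'->OH2''->OH3''->OH4''", "OH2'->OH3'->OH4'"]}
      ],
      "expected_count": 2
    },
    {
      "label": "F",
      "classes": {"first": "cis", "second": "trans"},
      "units": [
        {"id": "coop", "reversible": true,
         "fwd": ["OH4''->OH3''->OH2''->OH6'->OH2->OM", "OH4'->OH3'->OH2'"],
         "rev": ["OH2->OH6'->OH2''->OH3''->OH4''", "OH2'->OH3'->OH4'"]}
      ],
      "c6_rotamers": {"M''": "tg"},
      "expected_count": 2
    },
    {
      "label": "G",
      "classes": {"first": "trans", "second": "cis"},
      "units": [
        {"id": "fixed", "reversible": false,
         "fwd": ["OH4'->OH3'->OH2'->OM'", "OH4''->OH3''->OH2''->OM''",
                 "OH4->OH6'->OH6''"]}
      ],
      "expected_count": 1
    },
    {
      "label": "H",
      "classes": {"first": "trans", "second": "cis"},
      "units": [
        {"id": "fixed", "reversible": false,
         "fwd": ["OH4'->OH3'->OH2'->OM'", "OH4''->OH3''->OH2''->OM''",
                 "OH4->OH6'->OH6''->OM''"]}
      ],
      "expected_count": 1
    },
    {
      "label": "I",
      "classes": {"first": "trans", "second": "cis"},
      "units": [
        {"id": "fixed", "reversible": false,
         "fwd": ["OH4'->OH3'->OH2'->OM'", "OH3''->OH2''->OM''",
                 "OH4->OH6'->OH4''->OH6''"]}
      ],
      "expected_count": 1
    },
    {
      "label": "J",
      "classes": {"first": "trans", "second": "cis"},
      "units": [
        {"id": "armM1", "reversible": true,
         "fwd": ["OH4'->OH3'->OH2'->OM'"],
         "rev": ["OH2'->OH3'->OH4'"]},
        {"id": "fixed", "reversible": false,
         "fwd": ["OH4''->OM'", "OH3''->OH2''->OM''", "OH4->OH6'->OH6''"]}
      ],
      "expected_count": 2
    },
    {
      "label": "K",
      "classes": {"first": "trans", "second": "cis"},
      "units": [
        {"id": "armM1", "reversible": true,
         "fwd": ["OH4'->OH3'->OH2'->OM'"],
         "rev": ["OH2'->OH3'->OH4'"]},
        {"id": "fixed", "reversible": false,
         "fwd": ["OH4''->OM'", "OH3''->OH2''->OM''", "OH4->OH6'->OH6''->OM''"]}
      ],
      "expected_count": 2
    },
    {
      "label": "L",
      "classes": {"first": "trans", "second": "trans"},
      "units": [
        {"id": "fixed", "reversible": false,
         "fwd": ["OH2->OH6''->OH4''", "OH4'->OH3'->OH2'->OM'"]}
      ],
      "expected_count": 1
    },
    {
      "label": "M",
      "classes": {"first": "trans", "second": "trans"},
      "units": [
        {"id": "fixed", "reversible": false,
         "fwd": ["OH2->OH6''->OM''", "OH4'->OH3'->OH2'->OM'"]}
      ],
      "expected_count": 1
    }
  ]
}
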