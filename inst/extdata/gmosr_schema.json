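{
  "name": "GMOS-R",
  "version": "1.0",
  "provenance_note": "Region structure, item counts, permitted values and subscore maxima follow the published GMOS-R scoresheet (upper extremities 8 items / max 16, lower extremities 8 items / max 16, neck and trunk 2 items / max 4, sequence 1 item / max 2; total range 0-38). The per-item names are a synthetic reconstruction from the running-text descriptors (amplitude, speed, spatial range, rotations, beginning, end, stiffness); the printed sheet's exact wording of item labels and of the 0/1/2 anchors is not reproduced here. Counts and maxima are validated at load time.",
  "regions": [
    {
      "name": "UPPER_EXTREMITIES",
      "prefix": "ue",
      "max": 16,
      "items": ["amplitude", "speed", "spatial_range", "rotations",
                "beginning", "end", "smoothness", "stiffness"]
    },
    {
      "name": "LOWER_EXTREMITIES",
      "prefix": "le",
      "max": 16,
      "items": ["amplitude", "speed", "spatial_range", "rotations",
                "beginning", "end", "smoothness", "stiffness"]
    },
    {
      "name": "NECK_AND_TRUNK",
      "prefix": "nt",
      "max": 4,
      "items": ["neck", "trunk"]
    },
    {
      "name": "SEQUENCE",
      "prefix": "seq",
      "max": 2,
      "items": ["sequence"]
    }
  ],
  "allowed_values": {
    "detail": [0, 0.5, 1, 1.5, 2],
    "sequence": [0, 1, 2]
  }
}
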