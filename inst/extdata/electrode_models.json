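[
  {
    "model_name": "D05-illustrative",
    "comment": "Illustrative geometry only, not manufacturer-exact; supply your own catalog for clinical use.",
    "diameter_mm": 0.8,
    "tip_offset_mm": 0,
    "segments": [
      {"n_contacts": 5, "contact_length_mm": 2.0, "gap_after_mm": 1.5}
    ]
  },
  {
    "model_name": "D10-illustrative",
    "comment": "Illustrative geometry only, not manufacturer-exact.",
    "diameter_mm": 0.8,
    "tip_offset_mm": 0,
    "segments": [
      {"n_contacts": 10, "contact_length_mm": 2.0, "gap_after_mm": 1.5}
    ]
  },
  {
    "model_name": "D15-illustrative",
    "comment": "Illustrative geometry only, not manufacturer-exact.",
    "diameter_mm": 0.8,
    "tip_offset_mm": 0,
    "segments": [
      {"n_contacts": 15, "contact_length_mm": 2.0, "gap_after_mm": 1.5}
    ]
  },
  {
    "model_name": "G3x5-illustrative",
    "comment": "Grouped layout: three groups of five contacts, 1.5 mm within a group and 7 mm between groups (the last contact of a group carries the inter-group gap). Illustrative only.",
    "diameter_mm": 0.8,
    "tip_offset_mm": 0,
    "segments": [
      {"n_contacts": 4, "contact_length_mm": 2.0, "gap_after_mm": 1.5},
      {"n_contacts": 1, "contact_length_mm": 2.0, "gap_after_mm": 7.0},
      {"n_contacts": 4, "contact_length_mm": 2.0, "gap_after_mm": 1.5},
      {"n_contacts": 1, "contact_length_mm": 2.0, "gap_after_mm": 7.0},
      {"n_contacts": 5, "contact_length_mm": 2.0, "gap_after_mm": 1.5}
    ]
  }
]
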