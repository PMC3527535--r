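{
  "design_seed": 11,
  "designed_with": "design_unknotted_from(protein_k(), seed = 11, restarts = 40)",
  "chain_length": 40,
  "n_contacts": 40,
  "abs_contact_order": 16,
  "alexander_det": 1,
  "knot_type": "unknot",
  "core_range": {},
  "n_core_contacts": {},
  "verification_violations": []
}
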