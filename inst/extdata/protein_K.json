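{
  "design_seed": 3,
  "designed_with": "design_knotted_native(spec_protein_k(), seed = 3, restarts = 80, polish_cycles = 15)",
  "chain_length": 41,
  "n_contacts": 40,
  "abs_contact_order": 17.2,
  "alexander_det": 3,
  "knot_type": "trefoil",
  "core_range": [3, 22],
  "n_core_contacts": 8,
  "verification_violations": []
}
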