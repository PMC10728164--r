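{
  "description": "CAD evidence-ion sets localizing the three Ca2+ binding domains of ejected human cardiac TnC (P63316, 161 residues, full UniProt numbering). adduct_count is the number of Ca2+ retained by each fragment.",
  "chain_length": 161,
  "evidence": {
    "domain_III": {
      "precursor_mz": 2312,
      "ions": {
        "series": ["b", "b", "y", "y"],
        "index": [109, 115, 30, 52],
        "adduct_count": [0, 1, 0, 1]
      },
      "assumptions": []
    },
    "domain_IV": {
      "precursor_mz": 2316,
      "ions": {
        "series": ["b", "b", "y", "y"],
        "index": [140, 145, 16, 22],
        "adduct_count": [1, 2, 0, 1]
      },
      "assumptions": []
    },
    "domain_II": {
      "precursor_mz": 2321,
      "ions": {
        "series": ["b", "b", "y", "y"],
        "index": [65, 91, 85, 94],
        "adduct_count": [0, 1, 2, 3]
      },
      "assumptions": ["b65 carried zero Ca2+ (stated only implicitly in the source annotations)"]
    }
  }
}
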