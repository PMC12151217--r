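[
  {
    "identity": {
      "gene": "PTPN11",
      "transcript": "NM_002834.5",
      "hgvs_c": "c.922A>G",
      "hgvs_p": "p.(Asn308Asp)",
      "consequence": "missense",
      "residue_position": 308,
      "ref_aa": "N",
      "alt_aa": "D"
    },
    "probands": [
      {"phenotype_category": "consistent", "de_novo": "confirmed", "context": "clinical", "prenatal_features": [], "alt_cause_identified": false, "zygosity": "het"},
      {"phenotype_category": "consistent", "de_novo": "assumed", "context": "clinical", "prenatal_features": [], "alt_cause_identified": false, "zygosity": "het"},
      {"phenotype_category": "consistent", "de_novo": "assumed", "context": "clinical", "prenatal_features": [], "alt_cause_identified": false, "zygosity": "het"}
    ],
    "family": [],
    "population": {"grpmax_faf": 0, "subpopulations": []},
    "functional": {"assays": [
      {"assay_id": "phosphatase_activity", "result": "abnormal_expected"},
      {"assay_id": "p_erk", "result": "abnormal_expected"}
    ]},
    "computational": {"revel": 0.88, "splice_predictions": {}},
    "trans_observations": [],
    "passthrough_criteria": []
  }
]
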