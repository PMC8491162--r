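{
  "comment": "Published discriminant models: descriptor sets and training statistics. The numeric coefficients of the published equations are typeset as images in the source document and are not machine-recoverable, so they are not included; screening reproduces the published results from the printed per-compound DF values, and new models are refitted from data.",
  "models": [
    {
      "name": "DF_gen",
      "descriptors": ["SRW05", "CIC2", "GATS6m"],
      "coefficient_signs": {"SRW05": 1, "CIC2": -1, "GATS6m": -1},
      "N": 101,
      "wilks_lambda": 0.686,
      "F": 14.826,
      "p": 1e-05
    },
    {
      "name": "DF_1",
      "descriptors": ["MATS5i", "PCD", "GATS4e"],
      "coefficient_signs": {"MATS5i": -1, "PCD": -1},
      "N": 29,
      "wilks_lambda": 0.462,
      "F": 15.155,
      "p": 1e-05
    },
    {
      "name": "DF_2",
      "descriptors": ["JGI8", "Eig05_AEA_dm", "GATS8m"],
      "coefficient_signs": {},
      "N": 29,
      "wilks_lambda": 0.490,
      "F": 9.009,
      "p": 0.0003
    },
    {
      "name": "DF_3",
      "descriptors": ["GATS8m", "GATS5e", "P_VSA_LogP_5"],
      "coefficient_signs": {"GATS8m": 1},
      "N": 29,
      "wilks_lambda": 0.462,
      "F": 6.706,
      "p": 0.001
    }
  ]
}
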