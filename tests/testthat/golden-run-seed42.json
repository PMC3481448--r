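{
  "seed": 42,
  "n_pep": 907,
  "indices": {
    "peptide_id_rate": 0.910694597574421,
    "protein_quant_rate": 0.914285714285714,
    "peptide_missing_rate": 0.793770672546858,
    "protein_missing_rate": 0.17,
    "qerr": 0.562189478078118,
    "pct_markers_detected": 80,
    "err_knn_observed": 0.12,
    "err_lda_observed": 0.07,
    "err_knn_original": 0,
    "err_lda_original": 0
  }
}
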