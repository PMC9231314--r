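{
  "file": "table3_tpm.tsv",
  "format": "TSV with header row, UTF-8",
  "description": "TPM values for the viral pol and gag CDS features and the Actin-5C housekeeping gene across five transcriptome samples.",
  "columns": {
    "feature": "CDS feature id (pol, gag, Actin-5C)",
    "contig1..contig5": "TPM in the sample where the corresponding virus contig was assembled"
  },
  "invariants": [
    "15 numeric cells (3 features x 5 samples)",
    "every sample column sums to 1,000,000"
  ]
}
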