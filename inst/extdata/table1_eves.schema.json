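{
  "file": "table1_eves.tsv",
  "format": "TSV with header row, UTF-8",
  "description": "Curated EVE report records: one row per endogenous viral element call across three host genome assemblies (BGA1/2/3).",
  "columns": {
    "family": "viral family of the best hit",
    "eve_name": "EVE family short name (e.g. TotiEVE)",
    "locus_label": "orthologous locus label on the chromosome-level assembly, or 'np' (not placed)",
    "bga": "assembly index (1, 2 or 3; 3 is chromosome-level)",
    "best_hit": "best viral protein hit (blank cells of the printed table filled forward)",
    "aa_pct": "amino-acid percent identity of the best hit",
    "protein_class": "Capsid, RdRP or ORF1",
    "coordinates": "SEQID:START-END coordinate string; span = END - START"
  },
  "invariants": [
    "exactly 27 records",
    "locus_label in {PT, PR1, PR2, PR3, Rh, T1, T2, T3, Xi, np}",
    "coordinate spans range from 148 to 3750 nt"
  ]
}
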