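{
  "file": "table2_contigs.tsv",
  "format": "TSV with header row, UTF-8",
  "description": "RNA-seq datasets in which near-complete (>5 kb) contigs of the exogenous totivirus were assembled.",
  "columns": {
    "contig_name": "virus contig label",
    "sra_id": "SRA run accession",
    "bioproject": "SRA bioproject accession",
    "sample": "free-text sample description"
  },
  "invariants": [
    "exactly 5 records",
    "3 distinct bioprojects"
  ]
}
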