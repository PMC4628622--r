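{
  "ped": "fig1a.ped",
  "vcf": "fig1a_exome.vcf",
  "samples": ["IV:1", "IV:5", "IV:7", "IV:9", "V:6", "V:7", "V:8", "III:2", "IV:6", "IV:11"],
  "annotations": "fig1a_annotations.tsv",
  "validation": "fig1a_validation.tsv",
  "whitelist": "brain_expressed_genes.txt",
  "out_dir": "out",
  "scan": {
    "min_alt_reads": 20,
    "exception_ids": "IV:9"
  },
  "filters": {
    "maf_threshold": 0.01
  },
  "model": {
    "max_unaffected_carriers": 0,
    "exception_ids": "IV:9"
  }
}
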