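inputs:
  reference: reference.fasta
  fasta: cohort.fasta
  metadata: metadata.tsv
  haplogroup_defs: haplogroups.tsv
  lineage_map: ../lineage_map.tsv
  gene_model: gene_model.tsv
  code_table: ../vertebrate_mito_code.tsv
  usage_table: ../codon_usage_mito.tsv
cohort:
  heteroplasmy_min_ratio: 0.25
  homopolymer_min_run: 5
  heteroplasmy_policy: exclude_site_sample
  multiallelic_delta: total_variation
scan_rule: three_sd_about_zero
n_permutations: 199
seed: 7
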