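# Small end-to-end configuration: ~20,000 cells x 2,000 genes across the
# CRE screen (12,000 cells, 8 gRNAs/CRE) and the promoter screen
# (8,000 cells, 3 gRNAs/gene).
seed: 1
synth:
  annotation_params:
    n_genes: 2000
    n_chroms: 4
  regulatory_params:
    n_cres: 30
    indirect_fraction: 0.1
  cre_screen:
    n_cells: 12000
    grna_per_target: 8
    n_control_promoters: 5
  promoter_screen:
    n_cells: 8000
    grna_per_target: 3
    n_target_genes: 40
    propagate_trans: true
de:
  n_variable_genes: 300
enrichment:
  min_targets: 5
  min_degs: 3
cascade:
  min_shared: 2
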