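# Demo configuration for `epitet all` / run_all(): a small fully synthetic
# run that completes on one CPU in about a minute.
sim:
  genome_length: 200000
  n_chroms: 1
  n_genes: 40
  n_chip_peaks: 50
  n_rna_peaks: 40
  chip_replicates: 2
  hmerip_replicates: 2
  rna_replicates: 3
seed: 1
outdir: epitet_demo_run
dialect: embryo
consensus_window: 250
rna_p_threshold: 1.0e-05
metagene_flank: 2000
motif_k: 6
motif_shuffles: 30
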