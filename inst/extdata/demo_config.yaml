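# Demo: two clusters of five 20 kb genomes; cluster 1 carries one lsr2-like
# implant per genome, cluster 2 one whiB-like implant per genome.
simulation:
  n_clusters: 2
  genomes_per_cluster: 5
  genome_length_bp: 20000
  cluster_gc: [0.47, 0.60]
  within_cluster_divergence: 0.02
  implant_plan:
    - {cluster: 1, gene: lsr2-like, copies: 1, aa_divergence: 0.2}
    - {cluster: 2, gene: whiB-like, copies: 1, aa_divergence: 0.2}
  lifestyle_odds: 3
  seed: 11
params:
  k: 6
  prevalence_min: 2
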