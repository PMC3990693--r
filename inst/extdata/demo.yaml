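# Demo configuration for `sagscope run --config demo.yaml --outdir out`
# Analysis thresholds are the protocol defaults; simulation sizes are
# kept small so the full pipeline finishes in about a minute.
seed: 7
stages:
  simulate: yes
  qc: yes
  completeness: yes
  recruit: yes
  islands: yes
  bsr: yes
  phylotype: yes
simulate:
  n_genomes: 2
  genome_length: 30000
  gc: 0.34
  n_markers: 94
  n_accessory: 50
  n_ref_genomes: 60
  dropout: 0.005
  dup_rate: 0.005
  completeness: [0.4, 0.8]
  n_contigs: 6
  n_samples: 2
  n_reads: 500
  read_len_range: [250, 450]
  junk: [0.03, 0.03, 0.03, 0.03]
  divergence: 0.02
  n_coding_loci: 24
  n_islands: 4
qc:
  min_len: 100
  min_entropy: 70
recruit:
  min_aln_len: 200
  min_identity: 0.95
completeness:
  threshold: 0.98
islands:
  alpha: 0.05
bsr:
  threshold: 0.4
phylotype:
  threshold: 0.99
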