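# Demo run: 10 ingroup taxa + outgroup, one admixture pulse P4 -> P2
seed: 1
outdir: dscan_demo
stages: [simulate, dstat, trees, scan]
simulate:
  n_taxa: 10
  Ne: 10000
  mu: 5.0e-9
  n_windows: 500
  window_len: 50000
  ploidy: haploid
  pulse: {donor: P4, recipient: P2, time: 5000, gamma: 0.1}
  recomb: {segments: 10, scale: 0.7}
dstat:
  alpha: 0.01
  tree_constrained: true
scan:
  window: 50000
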