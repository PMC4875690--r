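# Demo pipeline configuration: a small two-population cohort with planted
# CNVs, sized to run end-to-end on one CPU in well under ten minutes.
out_dir: popcnv_demo
seed: 1
n_scaffolds: 3
scaffold_length: 1000000
bin_size: 500
n_samples:
  wild: 8
  domestic: 8
mean_depth: 6.7
n_neutral_events: 16
n_differentiated_events: 4
n_genes: 120
n_sd: 60
alpha: 0.05
min_length: 1500
max_q0: 0.5
min_support: 4
top_frac: 0.05
t_alpha: 0.05
n_perm: 200
window_size: 5000
heatmap: true
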