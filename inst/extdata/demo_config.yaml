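# Desk-scale demonstration run: two populations of 60 lines, 140 markers,
# four environments, 200 cross-validation resamples.
seed: 42
trait: grain_yield
populations:
  n_lines: 60
  n_markers_per_chrom: 20
  map_length_cM: 150
  seg_frac: [0.40, 0.60]
architecture:
  n_qtl: 30
environments: 4
qc:
  max_missing: 0.05
  maf: [0.05, 0.95]
cv:
  schemes: [within_within_same, across_within]
  predictor: rrblup
  n_resamples: 200
  n_folds: 5
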