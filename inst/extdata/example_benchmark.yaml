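# Minimal end-to-end benchmark: synthetic 6-type reference, two silver
# designs, both peak-selection strategies, baseline + NNLS deconvolver.
reference:
  n_cells: 600
  n_genes: 400
  n_peaks: 600
  n_cell_types: 6
  markers_per_type: 10
  marker_fold_change: 8
simulations:
  sparse_uniform:
    n_spots: 100
    zonation: uniform
    n_regions: 1
    mean_cell_types: 3
    mean_cells: 5
  zonated:
    n_spots: 100
    zonation: stripes
    n_regions: 4
    mean_cell_types: [10, 5, 10, 5]
    mean_cells: [15, 10, 15, 5]
strategies:
  hvp:
    strategy: highly_variable_peaks
    n_features: 200
  acc:
    strategy: highly_accessible
    n_features: 200
methods: [majority_oracle, nnls]
rare_types: [type01]
threshold: 0.05
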