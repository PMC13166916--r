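# Example run configuration for the ugci pipeline.
# Keys omitted here keep the package defaults (see default_config()).
seed: 42
out_dir: ugci_out
landscape:
  nrow: 200
  ncol: 200
  cell_size: 30
  fractions:
    forest: 0.30
    park: 0.10
    agricultural: 0.15
    roadside: 0.05
    water: 0.05
  # multiplicative component deficit applied at patch edges; 1 disables
  edge_deficit: 0.7
impervious_classes: [5]
green_classes: [1, 2, 3, 4]
edge_distance_m: 30
ternary:
  vertex_threshold: 0.5
  center_radius: 0.15
figures: false
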