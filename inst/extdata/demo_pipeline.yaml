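# Demo pipeline: synthesize a wrinkled nucleus, render and measure it, then
# compare monolayer roughness between a static-like (tall cells present) and
# a shear-like (flat) condition with a seeded permutation test.
seed: 1
stages:
- name: synth_nucleus
  params:
    volume: 400
    excess_area_pct: 15
    seed: 1
- name: render_nucleus
  params:
    voxel_size: [0.25, 0.25, 0.26]
    seed: 1
- name: measure_nuclei
  params: {}
- name: roughness_group
  params:
    label: static
    n_images: 3
    tall_cell_fraction: 0.3
    field_um: [30, 30]
    n_cells: 8
    seed: 1
- name: roughness_group
  params:
    label: shear
    n_images: 3
    tall_cell_fraction: 0.0
    field_um: [30, 30]
    n_cells: 8
    seed: 101
- name: stats_permutation
  params:
    group_a: static
    group_b: shear
    n_perm: 999
    seed: 1
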