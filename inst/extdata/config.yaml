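# Example pipeline configuration (desk-scale smoke settings).
seed: 7
profile_name: deepmirtar
n_pos: 200
n_neg: 200
ks: [1, 2, 3, 4, 5, 6]
impact_mode: mean
impact_window: 4
impact_top: 2
scan_n_pairs: 100
model:
  epochs: 60
layers: [cnn, birnn, dense1]
levels: [raw_unit, per_feature_map, all_units]
regions:
  seed2-6: {track: L, start: 2, len: 6}
  L4-4: {track: L, start: 4, len: 4}
  L13-4: {track: L, start: 13, len: 4}
region_pairs:
  - [seed2-6, L13-4]
  - [L4-4, L13-4]
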