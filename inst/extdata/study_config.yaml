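grid:
  d_min_um: 0.2
  d_max_um: 10.0
  intervals_per_decade: 128
maneuver:
  pressure_target_kpa: 4.0
  pressure_minimum_kpa: 1.0
  hold_s: 5.0
  exhale_flow_lpm: 30.0
  exhale_s: 6.0
filter:
  uam_cutoff_um: 3.0
  uam_steepness: 3.0
  uam_ref_flow_lpm: 60.0
  lung_min_diameter_um: 0.5
  diffusion_slope: 0.8
  sedimentation_slope: 70.0
background:
  concentration_pcm3: 10.0
  cmd_um: 0.3
  gsd: 2.0
  duration_s: 60.0
study:
  n_runs: 12
  lung_resistance_increment: 0.003
  seed: 1
devices:
- name: breezhaler
  resistance: 0.0216
  cmd_um: 1.605892
  gsd: 2.0
  emission_concentration_pcm3: 2000.0
  t_inh_s: 3.0
  capsule_flutter: yes
  lung_min_survival: 0.248513
  dose_type: single-dose, hard capsules
- name: ellipta
  resistance: 0.0286
  cmd_um: 0.971979
  gsd: 1.9
  emission_concentration_pcm3: 2000.0
  t_inh_s: 2.1
  capsule_flutter: no
  lung_min_survival: 0.389719
  dose_type: multidose, predispensed
- name: handihaler
  resistance: 0.0504
  cmd_um: 2.455774
  gsd: 2.0
  emission_concentration_pcm3: 2000.0
  t_inh_s: 1.4
  capsule_flutter: yes
  lung_min_survival: 0.594866
  dose_type: single-dose, hard capsules
- name: turbohaler
  resistance: 0.0313
  cmd_um: 0.793017
  gsd: 1.8
  emission_concentration_pcm3: 2000.0
  t_inh_s: 1.6
  capsule_flutter: no
  lung_min_survival: 0.176361
  dose_type: multidose, predispensed
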