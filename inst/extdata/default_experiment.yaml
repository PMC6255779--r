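seed: 1.0
phantom:
  grid:
    shape:
    - 431.0
    - 270.0
    - 72.0
    spacing_mm:
    - 0.13
    - 0.13
    - 0.25
    origin_mm:
    - 0.0
    - 0.0
    - 0.0
  lung_background_hu: -580.0
  structure_hu: -110.0
  feeder_radius_mm: 0.35
  print_undersize_mm: 0.05
  vessel_params:
    depth: 4.0
    root_radius_mm: 1.0
    radius_decay: 0.7
    segment_length_mm: 14.0
    length_decay: 0.8
    n_children: 2.0
    branch_angle_deg:
    - 20.0
    - 45.0
    root_start_mm:
    - 0.0
    - 18.5
    - 9.0
    root_dir:
    - 1.0
    - 0.0
    - 0.0
  nodules:
  - kind: spiked_sphere
    diameter_mm: 3.0
    center_mm:
    - 10.0
    - 10.0
    - 9.0
    n_spikes: 12.0
    spike_length_mm: 2.5
    spike_base_deg: 20.0
  - kind: sphere
    diameter_mm: 3.0
    center_mm:
    - 10.0
    - 27.0
    - 9.0
  - kind: spiked_sphere
    diameter_mm: 6.0
    center_mm:
    - 28.0
    - 10.0
    - 9.0
    n_spikes: 12.0
    spike_length_mm: 2.5
    spike_base_deg: 20.0
  - kind: sphere
    diameter_mm: 6.0
    center_mm:
    - 28.0
    - 27.0
    - 9.0
  - kind: spiked_sphere
    diameter_mm: 9.0
    center_mm:
    - 46.0
    - 10.0
    - 9.0
    n_spikes: 12.0
    spike_length_mm: 2.5
    spike_base_deg: 20.0
  - kind: sphere
    diameter_mm: 9.0
    center_mm:
    - 46.0
    - 27.0
    - 9.0
profiles:
- name: ct
  preset: yes
  noise_sigma_hu: 20.0
- name: hrct
  preset: yes
  noise_sigma_hu: 20.0
- name: spcct
  preset: yes
  noise_sigma_hu: 20.0
segmentation:
  repeats: 3.0
  perturb_vox: 1.0
registration:
  target_mm: 0.14
  search: no
mtf:
  n_slices: 8.0
  noise_sigma_hu: 5.0
  wires:
  - profile: ct
    wire_diameter_mm: 0.2
  - profile: hrct
    wire_diameter_mm: 0.2
  - profile: spcct
    wire_diameter_mm: 0.1
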