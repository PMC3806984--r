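geometry:
  tm_radius: 4.5
  tm_cone_depth: 1.5
  tm_thickness_tensa: 0.074
  tm_thickness_flaccida: 0.1
  flaccida_sector_deg: 60.0
  annulus_width: 0.1
  annulus_thickness: 1.2
  tm_tension: 150.0
  manubrium_fraction: 0.95
  ossicle_dims:
    malleus_handle: 0.3
    malleus_neck: 0.2
    malleus_head: 0.85
    incudomalleolar_joint: 0.15
    incus_body: 1.0
    incus_short_process: 0.5
    incus_long_process: 0.2
    incudostapedial_joint: 0.1
    stapes: 0.215
    cross_section_mm2: 6.4
    manubrium_thickness: 0.35
  footplate_area: 3.2
  n_cochlear_springs: 42
  n_lateral_springs: 4
  umbo_radius: 0.3
  mesh_size: 0.6
  ligaments:
    region:
    - anterior_malleal_ligament
    - posterior_incudal_ligament
    - tensor_tympani_muscle
    - stapedius_muscle
    segment:
    - malleus_head
    - incus_short_process
    - malleus_neck
    - stapes
    area_mm2:
    - 3.2
    - 0.4
    - 0.3
    - 0.2
    length_mm:
    - 2.0
    - 1.5
    - 2.0
    - 1.5
    dir_x:
    - 0.70711
    - 0.0
    - 0.70711
    - 0.0
    dir_y:
    - 0.0
    - 0.70711
    - 0.0
    - 0.70711
    dir_z:
    - 0.70711
    - 0.70711
    - 0.70711
    - 0.70711
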