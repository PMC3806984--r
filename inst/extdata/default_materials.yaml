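materials:
  tympanic_membrane_tensa:
    youngs_modulus: 3.34e+07
    density: 1200.0
    poisson: 0.3
    loss_factor: 0.7
  tympanic_membrane_flaccida:
    youngs_modulus: 1.11e+07
    density: 1200.0
    poisson: 0.3
    loss_factor: 0.7
  malleus_head:
    youngs_modulus: 1.2e+10
    density: 2550.0
    poisson: 0.3
    loss_factor: 0.05
  malleus_neck:
    youngs_modulus: 1.2e+10
    density: 4530.0
    poisson: 0.3
    loss_factor: 0.05
  malleus_handle:
    youngs_modulus: 1.2e+10
    density: 3700.0
    poisson: 0.3
    loss_factor: 0.05
  incus_body:
    youngs_modulus: 1.2e+10
    density: 2360.0
    poisson: 0.3
    loss_factor: 0.05
  incus_short_process:
    youngs_modulus: 1.2e+10
    density: 2260.0
    poisson: 0.3
    loss_factor: 0.05
  incus_long_process:
    youngs_modulus: 1.2e+10
    density: 5080.0
    poisson: 0.3
    loss_factor: 0.05
  stapes:
    youngs_modulus: 1.2e+10
    density: 2200.0
    poisson: 0.3
    loss_factor: 0.05
  incudomalleolar_joint:
    youngs_modulus: 1.2e+10
    density: 3200.0
    poisson: 0.3
    loss_factor: 0.7
  incudostapedial_joint:
    youngs_modulus: 600000.0
    density: 1200.0
    poisson: 0.3
    loss_factor: 0.7
  anterior_malleal_ligament:
    youngs_modulus: 2.1e+07
    density: 2500.0
    poisson: 0.3
    loss_factor: 0.7
  posterior_incudal_ligament:
    youngs_modulus: 650000.0
    density: 2500.0
    poisson: 0.3
    loss_factor: 0.7
  tensor_tympani_muscle:
    youngs_modulus: 260000.0
    density: 2500.0
    poisson: 0.3
    loss_factor: 0.7
  manubrium:
    youngs_modulus: 4.7e+09
    density: 1000.0
    poisson: 0.3
    loss_factor: 0.05
  stapedius_muscle:
    youngs_modulus: 520000.0
    density: 2500.0
    poisson: 0.3
    loss_factor: 0.7
  tympanic_annular_ligament:
    youngs_modulus: 600000.0
    density: 2500.0
    poisson: 0.3
    loss_factor: 1.2
springs:
  cochlear_total_k: 70.0
  cochlear_n: 42
  cochlear_total_c: 0.054
  stapedius_annular_k: 9.0
  lateral_k: 5000.0
  seal_loss: 0.7
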