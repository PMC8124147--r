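# Default scenario: 20 nm-radius gold nanospheres at volume fraction
# 5.6e-6 in a 2 mm x 2 mm tumor cylinder, full-coverage beam at 15 W/cm^2.
# All physical keys carry unit suffixes.
particle:
  radius_nm: 20
  material: Au
optics:
  n_medium: 1.40          # soft tissue; 1.33 for water
  wavelength_nm: ~        # ~ = scan 400-700 nm for the plasmon peak
  sigma_abs_nm2: ~        # override Mie with an explicit cross-section
  Qa: ~
  Qs_prime: ~
cell:
  radius_um: 10
tissue:
  radius_mm: 2
  depth_mm: 2
  cell_spacing_um: 50
  volume_fraction: 5.6e-6
  thermal_conductivity_w_mk: 0.55
  baseline_c: 37
  mu_a_medium_cm: 32.26
  mu_s_prime_medium_cm: 1.3
beam:
  shape: full             # full | spot | ring | spot_array
  intensity_wcm2: 15
grid:
  preset: coarse          # coarse | default | fine
  plane: false
damage:
  threshold_c: 52
  arrhenius_a_per_s: 3.1e98
  activation_energy_j_mol: 6.28e5
seed: 1
output_dir: ~
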