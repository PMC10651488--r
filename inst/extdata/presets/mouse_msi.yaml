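# Mechanically stimulating implant (MSI): the mouse_standard silicone disc
# with an embedded coin vibration motor, driven at 1.38 g amplitude / 203 Hz.
# Geometry, tissue layers and materials are identical to mouse_standard; the
# only deltas are the motor mass (coin motors are ~0.9 g) and the load record.
# The peak quasi-static force is loaded_mass * 1.38 * 9.8 N/kg (= 13.524 N/kg),
# with loaded mass = silicone disc mass + motor mass, derived at run time.
species: mouse
body_mass_kg: 0.025
lateral_extent_mm: 24
default_edge_length_mm: 1.0
layers:
  - name: muscle_bone
    thickness_mm: 3.0
    material:
      name: muscle_bone
      youngs_modulus_pa: 1.0e+5
      poisson_ratio: 0.45
      density_kg_m3: 1060
  - name: subcutis
    thickness_mm: 8.0
    material:
      name: fat
      youngs_modulus_pa: 3.0e+3
      poisson_ratio: 0.45
      density_kg_m3: 920
  - name: skin
    thickness_mm: 1.2
    material:
      name: skin
      youngs_modulus_pa: 1.0e+5
      poisson_ratio: 0.45
      density_kg_m3: 1100
implant:
  radius_mm: 7.75
  height_mm: 6.7
  layer: subcutis
  motor_mass_kg: 0.0009
  material:
    name: silicone
    youngs_modulus_pa: 5.0e+5
    poisson_ratio: 0.45
    density_kg_m3: 1100
load:
  kind: vibration
  amplitude_g: 1.38
  frequency_hz: 203
  direction: [1, 0, 0]
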