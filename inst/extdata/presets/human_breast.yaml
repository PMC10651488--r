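# Human silicone breast implant under static resting-tension loading.
#
# Provenance of values (configuration inputs):
# - implant: round breast implant scale, 12 cm diameter x 4 cm projection,
#   silicone-gel effective modulus O(100 kPa).
# - layers: chest wall (lumped muscle over rib), breast fat/gland envelope,
#   skin envelope; thicknesses are anatomical-scale modelling values.
# - tissue moduli: literature-scale small-strain values -- breast fat/gland
#   O(1-10 kPa), skin O(100 kPa), chest wall O(100 kPa).
# - static load: human dynamic resting tissue tension over the implant span,
#   order 1e+2 N -- roughly 1e4-fold the murine value at ~1e4-fold body-mass
#   ratio (allometric_force_scale with exponent 1 on the configured pair;
#   see the vignette for the scaling discussion).
species: human
body_mass_kg: 70
lateral_extent_mm: 160
default_edge_length_mm: 5.0
layers:
  - name: chest_wall
    thickness_mm: 20.0
    material:
      name: muscle_bone
      youngs_modulus_pa: 1.0e+5
      poisson_ratio: 0.45
      density_kg_m3: 1060
  - name: fat_gland
    thickness_mm: 50.0
    material:
      name: fat
      youngs_modulus_pa: 4.0e+3
      poisson_ratio: 0.45
      density_kg_m3: 940
  - name: skin
    thickness_mm: 5.0
    material:
      name: skin
      youngs_modulus_pa: 1.5e+5
      poisson_ratio: 0.45
      density_kg_m3: 1100
implant:
  radius_mm: 60.0
  height_mm: 40.0
  layer: fat_gland
  material:
    name: silicone_gel
    youngs_modulus_pa: 1.0e+5
    poisson_ratio: 0.45
    density_kg_m3: 970
load:
  kind: static_force
  magnitude_n: 105
  direction: [1, 0, 0]
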