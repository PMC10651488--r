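# Standard murine subcutaneous silicone disc implant, static loading.
#
# Provenance of values (configuration inputs, not outputs of this package):
# - implant: 1.55 cm diameter x 0.67 cm height silicone disc (device drawings).
# - layer thicknesses: dorsal mouse anatomy scale; skin ~1.2 mm (dermis +
#   epidermis, literature range 0.4-2 mm), subcutaneous pocket sized to host
#   the implant, thin muscle/bone support layer.
# - tissue moduli: literature-scale small-strain values -- skin O(100 kPa),
#   subcutaneous fat O(1-10 kPa), lumped muscle-over-bone O(100 kPa).
# - silicone modulus: compression-test scale for soft implant silicones
#   (O(0.1-1 MPa)); measure your own discs with youngs_modulus_from_curve().
# - static load: murine dynamic resting tissue tension, order 1e-2 N.
# Poisson ratios 0.45: soft tissue is nearly incompressible; 0.45 keeps the
# linear tetrahedron away from the locking/singular limit at 0.5.
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
  material:
    name: silicone
    youngs_modulus_pa: 5.0e+5
    poisson_ratio: 0.45
    density_kg_m3: 1100
load:
  kind: static_force
  magnitude_n: 0.02
  direction: [1, 0, 0]
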