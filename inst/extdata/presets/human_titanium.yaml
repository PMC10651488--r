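# Human titanium-cased implant (pacemaker/neurostimulator-like) variant.
# Identical to human_breast except for the implant material record
# (titanium alloy: E ~ 110 GPa, nu 0.3, rho 4500 kg/m^3): the comparison
# isolates the effect of implant stiffness on interface stress.
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
    name: titanium
    youngs_modulus_pa: 1.1e+11
    poisson_ratio: 0.3
    density_kg_m3: 4500
load:
  kind: static_force
  magnitude_n: 105
  direction: [1, 0, 0]
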