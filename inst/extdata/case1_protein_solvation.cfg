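# Protein solvation: charged transmembrane helix
calculation_type = protein_solvation
pqr_file_1 = Helix.pqr
grid_dimensions = 161, 161, 161
coarse_grid_lengths = 200, 200, 200
medium_grid_lengths = 100, 100, 100
fine_grid_lengths = 50, 50, 50
counter_ion = 1, 0.1, 2
counter_ion = -1, 0.1, 2
protein_dielectric = 5
solvent_dielectric = 80
membrane_dielectric = 2
headgroup_dielectric = 80
solution_method = lpbe
boundary_condition = focus
srad = 1.4
sdens = 10
temperature = 298.15
membrane_bottom = -21
membrane_thickness = 42
headgroup_thickness = 8
upper_exclusion_radius = 0
lower_exclusion_radius = 0
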