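# Ion solvation: K+ transfer into a membrane-embedded channel cavity
calculation_type = ion_solvation
pqr_file_1 = KcsA.pqr
pqr_file_2 = K_ion.pqr
grid_dimensions = 161, 161, 161
coarse_grid_lengths = 300, 300, 300
medium_grid_lengths = 120, 120, 120
fine_grid_lengths = 60, 60, 60
counter_ion = 1, 0.03, 2
counter_ion = -1, 0.03, 2
protein_dielectric = 2
solvent_dielectric = 80
membrane_dielectric = 2
headgroup_dielectric = 80
solution_method = lpbe
boundary_condition = focus
srad = 1.4
sdens = 10
temperature = 298.15
membrane_bottom = -12
membrane_thickness = 24
headgroup_thickness = 0
upper_exclusion_radius = 24
lower_exclusion_radius = 16
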