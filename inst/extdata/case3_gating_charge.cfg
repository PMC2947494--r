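# Gating charge: voltage-sensor valence of a hypothetical gating motion
calculation_type = gating_charge
pqr_file_1 = 3EMN.pqr
pqr_file_2 = closed_state.pqr
grid_dimensions = 161, 161, 161
coarse_grid_lengths = 300, 300, 300
medium_grid_lengths = 120, 120, 120
fine_grid_lengths = 60, 60, 60
counter_ion = 1, 0.1, 2
counter_ion = -1, 0.1, 2
protein_dielectric = 5
solvent_dielectric = 80
membrane_dielectric = 2
headgroup_dielectric = 80
solution_method = lpbe
boundary_condition = membrane_potential
srad = 1.4
sdens = 10
temperature = 298.15
membrane_bottom = -14
membrane_thickness = 28
headgroup_thickness = 0
upper_exclusion_radius = 18.5
lower_exclusion_radius = 18.5
membrane_potential = 50
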