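# SYNTHETIC stand-in for COD entry 7004704 (not the published structure).
# Same fragment composition: one 43-atom molecule + CHCl3 + H2O in P-1;
# geometry is artificial. Generated by cif2print::syntheticCod7004704().
data_cod7004704_synthetic
_cell_length_a    22.000000
_cell_length_b    16.000000
_cell_length_c    16.000000
_cell_angle_alpha 90.000000
_cell_angle_beta  90.000000
_cell_angle_gamma 90.000000
loop_
_space_group_symop_operation_xyz
'x,y,z'
'-x,-y,-z'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
C1 C 0.184151 0.165497 0.168705 1.0000
C2 C 0.252333 0.165497 0.168705 1.0000
C3 C 0.320515 0.165497 0.168705 1.0000
C4 C 0.184151 0.259247 0.168705 1.0000
N5 N 0.252333 0.259247 0.168705 1.0000
C6 C 0.320515 0.259247 0.168705 1.0000
C7 C 0.184151 0.352997 0.168705 1.0000
C8 C 0.252333 0.352997 0.168705 1.0000
C9 C 0.320515 0.352997 0.168705 1.0000
C10 C 0.184151 0.165497 0.262455 1.0000
N11 N 0.252333 0.165497 0.262455 1.0000
C12 C 0.320515 0.165497 0.262455 1.0000
N13 N 0.184151 0.259247 0.262455 1.0000
C14 C 0.252333 0.259247 0.262455 1.0000
N15 N 0.320515 0.259247 0.262455 1.0000
C16 C 0.184151 0.352997 0.262455 1.0000
N17 N 0.252333 0.352997 0.262455 1.0000
C18 C 0.320515 0.352997 0.262455 1.0000
C19 C 0.184151 0.165497 0.356205 1.0000
C20 C 0.252333 0.165497 0.356205 1.0000
C21 C 0.320515 0.165497 0.356205 1.0000
C22 C 0.184151 0.259247 0.356205 1.0000
N23 N 0.252333 0.259247 0.356205 1.0000
C24 C 0.320515 0.259247 0.356205 1.0000
C25 C 0.184151 0.352997 0.356205 1.0000
C26 C 0.252333 0.352997 0.356205 1.0000
C27 C 0.320515 0.352997 0.356205 1.0000
H28 H 0.157908 0.129412 0.132620 1.0000
H29 H 0.252333 0.121303 0.124511 1.0000
H30 H 0.346758 0.129412 0.132620 1.0000
H31 H 0.152010 0.259247 0.124511 1.0000
H32 H 0.352656 0.259247 0.124511 1.0000
H33 H 0.157908 0.389081 0.132620 1.0000
H34 H 0.252333 0.397191 0.124511 1.0000
H35 H 0.346758 0.389081 0.132620 1.0000
H36 H 0.152010 0.121303 0.262455 1.0000
H37 H 0.352656 0.121303 0.262455 1.0000
H38 H 0.152010 0.397191 0.262455 1.0000
H39 H 0.352656 0.397191 0.262455 1.0000
H40 H 0.157908 0.129412 0.392289 1.0000
H41 H 0.252333 0.121303 0.400399 1.0000
H42 H 0.346758 0.129412 0.392289 1.0000
H43 H 0.152010 0.259247 0.400399 1.0000
S1 C 0.250000 0.700000 0.288499 1.0000
S2 H 0.250000 0.700000 0.356624 1.0000
S3 Cl 0.325854 0.700000 0.251626 1.0000
S4 Cl 0.212073 0.790326 0.251626 1.0000
S5 Cl 0.212073 0.609674 0.251626 1.0000
W1 O 0.539096 0.030637 0.600000 1.0000
W2 H 0.582733 0.030637 0.600000 1.0000
W3 H 0.528171 0.088726 0.600000 1.0000
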