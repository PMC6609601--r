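tissue,sub_region,site_label,site_id,slice_hole,chip_1,chip_2,chip_3
bone_marrow,calvarium,anterior_calvarium,ant_calvarium,2 (1),H3,H7,H8
bone_marrow,calvarium,left_calvarium,left_calvarium,2 (2),G4,G11,G12
bone_marrow,calvarium,right_calvarium,right_calvarium,2 (3),F6,F12,G3
bone_marrow,ramus,right_ramus,right_ramus,6 (19),AS1,AS4,AS7
bone_marrow,ramus,left_ramus,left_ramus,6 (17),P6,Q1,R1
bone_marrow,cervical_spine,center_cervical_spine,cervical_spine,8 (21),N2,O1,O3
bone,calvarium,anterior_calvarium,ant_calvarium,2 (1),H3,H7,H8
bone,calvarium,left_calvarium,left_calvarium,2 (2),G4,G11,G12
bone,calvarium,right_calvarium,right_calvarium,2 (3),F6,F12,G3
bone,ramus,right_ramus,right_ramus,6 (19),AS1,AS4,AS7
bone,ramus,left_ramus,left_ramus,6 (17),P6,Q1,R1
bone,cervical_spine,center_cervical_spine,cervical_spine,8 (21),N2,O1,O3
brain,brain,midbrain,midbrain_a,3 (6),D2,E2,E3
brain,brain,midbrain,midbrain_b,3 (7),E11,F2,F5
brain,brain,pituitary,pituitary,4 (12),K3,K6,K12
oesophagus,oesophagus,oesophagus,oesophagus,8 (21),A6,L2,L3
salivary_gland,parotid,right_parotid_gland,right_ramus,6 (19),AS1,AS4,AS7
salivary_gland,parotid,left_parotid_gland,left_ramus,6 (17),P6,Q1,R1
salivary_gland,submandibular,right_submandibular_gland,right_ramus,6 (19),AS1,AS4,AS7
salivary_gland,submandibular,left_submandibular_gland,left_ramus,6 (17),P6,Q1,R1
salivary_gland,sublingual,center_sublingual_gland,sublingual,6 (18),O4,O7,O8
skin,skin,right_lens_of_eye,right_eye,4 (15),B3,B4,B9
skin,skin,left_lens_of_eye,left_eye,4 (16),C6,C7,C11
skin,skin,left_back_of_neck,back_of_neck,6 (20),AS10,J3,J8
thyroid,thyroid,left_thyroid,left_thyroid,8 (22),M7,N1,H10
thyroid,thyroid,right_thyroid,right_thyroid,8 (23),M1,M6,H9
extrathoracic_airways,extrathoracic_airways,right_maxillary_sinus,right_eye,4 (15),B3,B4,B9
extrathoracic_airways,extrathoracic_airways,left_nasopharynx,pituitary,4 (12),K3,K6,K12
extrathoracic_airways,extrathoracic_airways,right_parotid,right_ramus,6 (19),AS1,AS4,AS7
extrathoracic_airways,extrathoracic_airways,left_parotid,left_ramus,6 (17),P6,Q1,R1
extrathoracic_airways,extrathoracic_airways,right_submandibular_gland,right_ramus,6 (19),AS1,AS4,AS7
extrathoracic_airways,extrathoracic_airways,left_submandibular_gland,left_ramus,6 (17),P6,Q1,R1
extrathoracic_airways,extrathoracic_airways,center_sublingual_gland,sublingual,6 (18),O4,O7,O8
extrathoracic_airways,extrathoracic_airways,oesophagus,oesophagus,8 (21),A6,L2,L3
lymph_nodes,lymph_nodes,right_parotid_gland,right_ramus,6 (19),AS1,AS4,AS7
lymph_nodes,lymph_nodes,left_parotid_gland,left_ramus,6 (17),P6,Q1,R1
lymph_nodes,lymph_nodes,right_submandibular_gland,right_ramus,6 (19),AS1,AS4,AS7
lymph_nodes,lymph_nodes,left_submandibular_gland,left_ramus,6 (17),P6,Q1,R1
lymph_nodes,lymph_nodes,center_sublingual_gland,sublingual,6 (18),O4,O7,O8
lymph_nodes,lymph_nodes,left_thyroid,left_thyroid,8 (22),M7,N1,H10
lymph_nodes,lymph_nodes,right_thyroid,right_thyroid,8 (23),M1,M6,H9
muscles,muscles,right_parotid_gland,right_ramus,6 (19),AS1,AS4,AS7
muscles,muscles,left_parotid_gland,left_ramus,6 (17),P6,Q1,R1
muscles,muscles,right_submandibular_gland,right_ramus,6 (19),AS1,AS4,AS7
muscles,muscles,left_submandibular_gland,left_ramus,6 (17),P6,Q1,R1
muscles,muscles,center_sublingual_gland,sublingual,6 (18),O4,O7,O8
muscles,muscles,left_thyroid,left_thyroid,8 (22),M7,N1,H10
muscles,muscles,right_thyroid,right_thyroid,8 (23),M1,M6,H9
oral_mucosa,oral_mucosa,right_parotid_gland,right_ramus,6 (19),AS1,AS4,AS7
oral_mucosa,oral_mucosa,left_parotid_gland,left_ramus,6 (17),P6,Q1,R1
oral_mucosa,oral_mucosa,right_submandibular_gland,right_ramus,6 (19),AS1,AS4,AS7
oral_mucosa,oral_mucosa,left_submandibular_gland,left_ramus,6 (17),P6,Q1,R1
oral_mucosa,oral_mucosa,center_sublingual_gland,sublingual,6 (18),O4,O7,O8
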