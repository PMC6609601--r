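site_id,absorbed_dose_ugy
ant_calvarium,4.1
left_calvarium,6.3
right_calvarium,5.8
right_ramus,61.5
left_ramus,58.9
cervical_spine,31.2
midbrain_a,12.4
midbrain_b,11.8
pituitary,16.5
oesophagus,9.7
sublingual,48.3
right_eye,6.9
left_eye,7.2
back_of_neck,18.4
left_thyroid,14.6
right_thyroid,13.9
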