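tissue,sub_region,fraction_pct,w_t,is_remainder
bone_marrow,calvarium,11.6,0.12,0
bone_marrow,ramus,1.1,0.12,0
bone_marrow,cervical_spine,2.7,0.12,0
bone,calvarium,11.8,0.01,0
bone,ramus,1.3,0.01,0
bone,cervical_spine,3.4,0.01,0
brain,brain,100,0.01,0
oesophagus,oesophagus,10,0.04,0
salivary_gland,parotid,100,0.01,0
salivary_gland,submandibular,100,0.01,0
salivary_gland,sublingual,100,0.01,0
skin,skin,5,0.01,0
thyroid,thyroid,100,0.04,0
extrathoracic_airways,extrathoracic_airways,100,0.12,1
lymph_nodes,lymph_nodes,5,0.12,1
muscles,muscles,5,0.12,1
oral_mucosa,oral_mucosa,100,0.12,1
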