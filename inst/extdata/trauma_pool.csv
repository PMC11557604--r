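case_id,category,n_injured,bones,injured_elements
97910,sports accident,1,frontal,frontal_2
89829,sports accident,3,mandible_L;mandible_R,mandible_L_1;mandible_L_2;mandible_R_4
AE-1,animal encounter,4,parietal_R,parietal_R_1;parietal_R_2;parietal_R_3;parietal_R_4
AE-2,animal encounter,6,parietal_L;temporal_L;occipital,parietal_L_1;parietal_L_2;temporal_L_1;temporal_L_2;occipital_1;occipital_3
Case 1,animal encounter,6,zygomatic_R;maxilla_R,zygomatic_R_1;zygomatic_R_2;maxilla_R_1;maxilla_R_2;maxilla_R_3;maxilla_R_4
Case 2,animal encounter,5,zygomatic_L;maxilla_L,zygomatic_L_1;zygomatic_L_2;maxilla_L_1;maxilla_L_2;maxilla_L_3
Case 3,animal encounter,9,mandible_L;zygomatic_L;maxilla_L;maxilla_R,mandible_L_1;mandible_L_4;zygomatic_L_1;zygomatic_L_2;maxilla_L_1;maxilla_L_2;maxilla_L_3;maxilla_R_1;maxilla_R_2
44849,animal encounter,9,frontal;maxilla_R;nasal_R;zygomatic_R,frontal_2;frontal_3;maxilla_R_1;maxilla_R_2;maxilla_R_3;nasal_R_1;nasal_R_2;zygomatic_R_1;zygomatic_R_2
187674,fall from a height,1,occipital,occipital_4
56134,fall from a height,2,mandible_R,mandible_R_1;mandible_R_4
FT-1,fall from a height,34,frontal;parietal_L;parietal_R;temporal_L;temporal_R;occipital;mandible_L;mandible_R;nasal_L,frontal_1;frontal_2;frontal_3;frontal_4;parietal_L_1;parietal_L_2;parietal_L_3;parietal_L_4;parietal_R_1;parietal_R_2;parietal_R_3;parietal_R_4;temporal_L_1;temporal_L_2;temporal_L_3;temporal_L_4;temporal_R_1;temporal_R_2;temporal_R_3;temporal_R_4;occipital_1;occipital_2;occipital_3;occipital_4;mandible_L_1;mandible_L_2;mandible_L_3;mandible_L_4;mandible_R_1;mandible_R_2;mandible_R_3;mandible_R_4;nasal_L_1;nasal_L_2
FT-2,fall from a height,3,mandible_L;mandible_R,mandible_L_1;mandible_L_2;mandible_R_2
FT-3,fall from a height,1,maxilla_L,maxilla_L_3
FT-4,fall from a height,19,frontal;parietal_L;temporal_L;mandible_L;maxilla_L,frontal_1;frontal_2;frontal_3;frontal_4;parietal_L_1;parietal_L_2;parietal_L_3;parietal_L_4;temporal_L_1;temporal_L_2;temporal_L_3;temporal_L_4;mandible_L_1;mandible_L_2;mandible_L_3;mandible_L_4;maxilla_L_1;maxilla_L_2;maxilla_L_3
FT-12,fall from a height,8,temporal_L;temporal_R;parietal_L;parietal_R;occipital,temporal_L_1;temporal_R_1;parietal_L_1;parietal_L_2;parietal_R_1;parietal_R_2;occipital_1;occipital_2
FT-14,fall from a height,4,temporal_R;parietal_R;occipital,temporal_R_1;parietal_R_3;occipital_1;occipital_2
FT-8,fall from a height,4,frontal;maxilla_L,frontal_1;frontal_3;maxilla_L_1;maxilla_L_3
FT-16,fall from a height,8,frontal;occipital;parietal_L;maxilla_L,frontal_1;frontal_2;occipital_1;occipital_3;parietal_L_1;parietal_L_2;maxilla_L_1;maxilla_L_3
23979,fall from a height,4,frontal;parietal_R,frontal_2;frontal_4;parietal_R_1;parietal_R_3
88120,miscellaneous clinical,3,mandible_R;temporal_R,mandible_R_3;mandible_R_4;temporal_R_1
91256,miscellaneous clinical,2,nasal_L;nasal_R,nasal_L_1;nasal_R_1
90655,miscellaneous clinical,2,frontal,frontal_1;frontal_3
68197,miscellaneous clinical,2,nasal_L;nasal_R,nasal_L_1;nasal_R_1
13084,miscellaneous clinical,1,parietal_L,parietal_L_1
73267,projectile/arrow shot,1,mandible_L,mandible_L_3
72101,projectile/arrow shot,1,frontal,frontal_3
BFT-2,violence,2,parietal_R,parietal_R_1;parietal_R_2
BFT-3,violence,4,occipital;temporal_L,occipital_1;occipital_3;occipital_4;temporal_L_2
BFT-8,violence,19,frontal;nasal_L;nasal_R;zygomatic_L;zygomatic_R;maxilla_L;maxilla_R;mandible_L;mandible_R,frontal_3;frontal_4;nasal_L_1;nasal_L_2;nasal_R_1;nasal_R_2;zygomatic_L_1;zygomatic_L_2;zygomatic_R_1;zygomatic_R_2;maxilla_L_1;maxilla_L_2;maxilla_L_3;maxilla_R_1;maxilla_R_2;maxilla_R_3;mandible_L_1;mandible_L_2;mandible_R_1
BFT-10,violence,5,zygomatic_L;maxilla_L,zygomatic_L_1;zygomatic_L_2;maxilla_L_1;maxilla_L_2;maxilla_L_3
BFT-15,violence,19,frontal;temporal_L;nasal_L;nasal_R;mandible_L;mandible_R;maxilla_L;maxilla_R,frontal_1;frontal_3;frontal_4;temporal_L_1;temporal_L_2;temporal_L_3;temporal_L_4;nasal_L_1;nasal_L_2;nasal_R_1;nasal_R_2;mandible_L_1;mandible_L_2;mandible_L_3;mandible_R_1;maxilla_L_1;maxilla_L_2;maxilla_L_3;maxilla_R_1
155152,violence,1,mandible_R,mandible_R_4
82151,violence,1,mandible_L,mandible_L_1
57289,violence,2,mandible_L,mandible_L_1;mandible_L_2
54433,violence,4,mandible_L;mandible_R,mandible_R_1;mandible_R_2;mandible_L_1;mandible_L_2
48597,violence,2,zygomatic_L,zygomatic_L_1;zygomatic_L_2
47820,violence,1,zygomatic_R,zygomatic_R_2
97910-V,violence,1,maxilla_R,maxilla_R_4
89829-V,violence,4,nasal_L;nasal_R;maxilla_L,nasal_L_1;nasal_L_2;nasal_R_1;maxilla_L_1
V-40,violence,3,temporal_R;parietal_R,temporal_R_1;parietal_R_1;parietal_R_2
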