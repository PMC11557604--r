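bone,ess
frontal,32
parietal_L,32
parietal_R,33
temporal_L,26
temporal_R,27
occipital,30
nasal_L,5
nasal_R,5
zygomatic_L,7
zygomatic_R,7
maxilla_L,14
maxilla_R,14
mandible_L,34
mandible_R,35
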