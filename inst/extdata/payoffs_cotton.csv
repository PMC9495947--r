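crop,interaction,focal_species,focal_genotype,opponent_species,opponent_genotype,rho_s,provenance,note
cotton,inter,SF,SS,HA,SS,0.60,printed,interspecific bioassay cotton; Sf-SS survival against Ha-SS
cotton,inter,HA,SS,SF,SS,0.15,printed,interspecific bioassay cotton; Ha-SS survival against Sf-SS
cotton,inter,SF,SS,HA,RR,0.57,printed,interspecific bioassay cotton; Sf-SS survival against Ha-RR
cotton,inter,SF,RR,HA,SS,0.20,printed,interspecific bioassay cotton; Sf-RR survival against Ha-SS
cotton,inter,HA,SS,SF,RR,0.00,printed,interspecific bioassay cotton; Ha-SS survival against Sf-RR
cotton,intra,HA,SS,HA,SS,0.375,printed,intraspecific bioassay cotton; Ha-SS vs Ha-SS
cotton,intra,HA,RR,HA,SS,0.175,printed,intraspecific bioassay cotton; Ha-RR vs Ha-SS
cotton,intra,HA,RR,HA,RR,0.40,printed,intraspecific bioassay cotton; Ha-RR vs Ha-RR
cotton,intra,SF,RR,SF,SS,0.175,printed,intraspecific bioassay cotton; Sf-RR vs Sf-SS
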