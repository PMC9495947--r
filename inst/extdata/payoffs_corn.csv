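crop,interaction,focal_species,focal_genotype,opponent_species,opponent_genotype,rho_s,provenance,note
corn,inter,HA,SS,SF,RR,0.00,printed,interspecific bioassay corn; Ha-SS survival against Sf-RR
corn,inter,SF,RR,HA,SS,0.25,printed,interspecific bioassay corn; Sf-RR survival against Ha-SS
corn,inter,HA,RR,SF,SS,0.30,printed,interspecific bioassay corn; Ha-RR survival against Sf-SS
corn,inter,SF,SS,HA,RR,0.55,printed,interspecific bioassay corn; Sf-SS survival against Ha-RR
corn,intra,HA,SS,HA,SS,0.25,printed,intraspecific bioassay corn; Ha-SS vs Ha-SS
corn,intra,HA,RR,HA,SS,0.125,printed,intraspecific bioassay corn; Ha-RR vs Ha-SS
corn,intra,HA,RR,HA,RR,0.38,printed,intraspecific bioassay corn; Ha-RR vs Ha-RR
corn,intra,SF,SS,SF,SS,0.325,printed,intraspecific bioassay corn; Sf-SS vs Sf-SS
corn,intra,SF,RR,SF,SS,0.500,printed,intraspecific bioassay corn; Sf-RR vs Sf-SS
corn,intra,SF,RR,SF,RR,0.475,printed,intraspecific bioassay corn; Sf-RR vs Sf-RR
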