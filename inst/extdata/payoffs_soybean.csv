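crop,interaction,focal_species,focal_genotype,opponent_species,opponent_genotype,rho_s,provenance,note
soybean,inter,HA,SS,SF,SS,0.85,printed,interspecific bioassay soybean; Ha-SS survival against Sf-SS
soybean,inter,SF,SS,HA,SS,0.55,printed,interspecific bioassay soybean; Sf-SS survival against Ha-SS
soybean,inter,SF,RR,HA,RR,0.25,printed,interspecific bioassay soybean; Sf-RR survival against Ha-RR
soybean,intra,HA,SS,HA,SS,0.725,printed,intraspecific bioassay soybean; Ha-SS vs Ha-SS
soybean,intra,HA,RR,HA,SS,0.475,printed,intraspecific bioassay soybean; Ha-RR vs Ha-SS
soybean,intra,HA,RR,HA,RR,0.55,printed,intraspecific bioassay soybean; Ha-RR vs Ha-RR
soybean,intra,SF,SS,SF,SS,0.20,printed,intraspecific bioassay soybean; Sf-SS vs Sf-SS
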