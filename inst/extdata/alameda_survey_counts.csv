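stratum_type,stratum,n_LL,n_LF,n_FF
species,Cx. erythrothorax,126,0,0
species,Cx. tarsalis,401,57,49
species,Cx. pipiens,208,226,310
region,bayside,519,136,89
region,inland,216,147,270
land_use,wildlife,296,94,94
land_use,urban,123,80,100
land_use,industrial,251,83,115
land_use,agriculture,65,26,50
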