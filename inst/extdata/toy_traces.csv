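region,well_id,channel,cycle,intensity
protein,W1,FAM,1,0.101
protein,W1,FAM,2,0.099
protein,W1,FAM,3,0.102
protein,W1,FAM,4,0.100
protein,W1,FAM,5,0.103
protein,W1,FAM,6,0.098
protein,W1,FAM,7,0.101
protein,W1,FAM,8,0.100
protein,W2,FAM,1,0.100
protein,W2,FAM,2,0.105
protein,W2,FAM,3,0.120
protein,W2,FAM,4,0.300
protein,W2,FAM,5,0.700
protein,W2,FAM,6,0.950
protein,W2,FAM,7,1.050
protein,W2,FAM,8,1.080
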