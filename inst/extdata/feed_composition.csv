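feed,DM,NDF,ADF,lignin,N,dmi_kg_d
hay,0.875,0.700,0.379,0.061,0.0756,3.31
straw,0.878,0.846,0.536,0.10,0.0359,1.06
supplement,0.90,0.24,0.16,0.02,0.0224,0.335
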