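diet,NDF,ADF,N,lignin
hay,0.55,0.33,0.025,0.11
straw,0.62,0.42,0.018,0.13
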