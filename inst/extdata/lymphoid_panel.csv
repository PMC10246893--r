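marker,B,NK,CD4 T,CD4 T,CD8 T,CD8 T,gd T,gd T,dn T,dp T
CD45,1,1,1,1,1,1,1,1,1,1
CD20,1,0,0,0,0,0,0,0,0,0
CD3,0,0,1,1,1,1,1,1,1,1
TCRgd,0,0,0,0,0,0,1,1,0,0
CD4,0,0,1,1,0,0,0,1,0,1
CD8,0,0,0,0,1,1,0,0,0,1
CD57,0,1,0,1,0,1,0,0,0,0
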