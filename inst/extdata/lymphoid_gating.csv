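label,CD45,CD20,CD3,TCRgd,CD4,CD8,CD57
B,pos,pos,any,any,any,any,any
NK,pos,neg,neg,any,any,any,pos
CD4 T,pos,neg,pos,neg,pos,neg,any
CD8 T,pos,neg,pos,neg,neg,pos,any
gd T,pos,neg,pos,pos,any,any,any
dn T,pos,neg,pos,neg,neg,neg,any
dp T,pos,neg,pos,neg,pos,pos,any
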