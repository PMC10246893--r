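label,CD45,CD1c,CD207,HLA-DR,Tryptase,MPO,Siglec8,CD123
mast,pos,any,any,any,pos,any,any,any
dDC,pos,pos,neg,any,any,any,any,any
LC,pos,neg,pos,any,any,any,any,any
CD207+ dDC,pos,pos,pos,any,any,any,any,any
neutrophil,pos,neg,neg,any,neg,pos,neg,any
eosinophil,pos,neg,neg,any,neg,neg,pos,neg
basophil,pos,neg,neg,any,any,neg,pos,pos
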