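landcover,V,BEF,D,R,CF
forest,148.0,1.43,0.66,0.26,0.50
park,60.0,1.43,0.66,0.26,0.50
agricultural,8.0,1.30,0.50,0.25,0.47
roadside,148.0,1.43,0.66,0.26,0.50
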