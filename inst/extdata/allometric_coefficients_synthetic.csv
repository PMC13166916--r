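species,a,b
ginkgo,0.0074,2.57
zelkova,0.0112,2.45
cherry,0.0096,2.50
metasequoia,0.0061,2.63
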