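section,alpha,beta,c
P,5.59,7.96e-3,-1.66e-4
M,23.8,1.70e-3,-1.11e-2
A,1450,2.05e-4,-2.76e-1
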