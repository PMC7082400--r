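# treatment: thiosulfate
day,pH,total_s_mM_S,SO4^2-,S^2-,S2O3^2-,SO3^2-,S0,S0_particulate
0,2.8,25.3,0,0,12.65,0,0,0
2,2.4,25.3,7.8,0,0.720000000000001,0,0,0
4,2.5,25.3,7.8,0,3.1,0.4,4,0
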