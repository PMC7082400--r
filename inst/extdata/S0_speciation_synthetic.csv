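# treatment: S0
day,pH,total_s_mM_S,SO4^2-,S^2-,S2O3^2-,SO3^2-,S0,S0_particulate
0,4,0,0,0,0,0,0,311.915159076731
1,3.2,1.95,0.685,0,0,0,0,309.965159076731
2,2.8,5.85,2.055,0,0,0,0,306.065159076731
3,2.5,12.87,4.521,0,0,0,0,299.045159076731
4,1.9,23.4,8.22,0,0,0,0,288.515159076731
5,1.5,39,13.7,0,0,0,0,272.915159076731
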