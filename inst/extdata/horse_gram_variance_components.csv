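TRAIT,SIGMA2_G,SIGMA2_GEI,SIGMA2_E,N_ENV,N_REP
DM,3.13,5.42,37.20,6,6
NC,966.70,217.00,69.41,6,6
NP,5488.00,841.70,439.90,6,6
NPC,0.06,0.11,0.03,6,6
NS,0.114,0.175,0.074,6,6
YD,25425.00,1663.00,2374.00,6,6
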