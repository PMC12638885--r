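TRAIT,XO,XS,SD_PCT,SG_PCT,SENSE
NC,160.00,201.00,25.70,24.70,increase
NP,407.00,524.00,28.80,28.00,increase
NPC,3.45,3.94,14.20,10.80,increase
NS,5.40,5.94,9.94,7.81,increase
YD,942.00,1229.00,30.40,30.00,increase
DM,122.00,122.00,0.05,0.03,increase
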