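GEN,NAME,DM,NC,NP,NPC,NS,YD
G1,TNAU-HG-007,123.69,204.61,535.07,4.16,6.28,1335.28
G2,TNAU-HG-031,121.63,122.91,397.31,3.14,5.44,852.79
G3,TNAU-HG-070,122.41,205.19,518.81,3.90,5.89,1245.03
G4,TNAU-HG-034,123.66,186.02,397.68,3.12,5.51,1051.19
G5,TNAU-HG-019,120.37,169.59,444.75,3.61,5.32,864.61
G6,TNAU-HG-027,119.89,131.54,423.53,3.56,5.33,916.89
G7,TNAU-HG-049,124.45,169.68,354.73,3.34,5.96,908.03
G8,TNAU-HG-018,121.53,193.73,521.47,3.75,5.84,1122.83
G9,TNAU-HG-062,120.92,165.18,389.51,3.63,5.02,818.04
G10,TNAU-HG-057,121.96,170.32,448.20,3.29,5.48,886.31
G11,TNAU-HG-073,120.90,124.84,409.58,3.55,5.35,854.22
G12,TNAU-HG-083,120.80,145.97,351.02,3.59,5.44,909.15
G13,TNAU-HG-036,120.48,170.57,325.07,3.26,5.24,863.82
G14,TNAU-HG-030,118.66,126.23,417.03,3.28,4.96,729.49
G15,TNAU-HG-082,121.10,198.09,320.01,3.61,4.86,953.69
G16,TNAU-HG-025,119.56,142.57,428.23,3.16,5.18,804.59
G17,TNAU-HG-053,118.50,115.91,380.95,3.19,5.09,790.24
G18,TNAU-HG-016,118.68,127.36,458.40,3.36,4.96,840.80
G19,TNAU-HG-071,123.53,122.58,349.50,3.49,5.39,825.18
G20,TNAU-HG-075,120.10,118.10,377.86,3.05,4.92,784.59
G21,TNAU-HG-065,122.96,114.76,340.12,2.98,4.84,758.92
G22,TNAU-HG-089,120.63,199.20,521.97,3.93,5.76,1212.73
G23,TNAU-HG-032,123.66,156.34,418.26,3.47,5.55,863.36
G24,TNAU-HG-003,121.51,122.88,357.57,3.09,5.11,810.48
G25,TNAU-HG-081,114.66,194.86,485.29,3.63,6.28,1217.08
G26,TNAU-HG-011,120.59,137.02,391.01,3.23,5.39,768.52
G27,TNAU-HG-039,119.98,199.13,517.42,3.63,5.50,1160.29
G28,TNAU-HG-076,122.71,187.07,309.85,3.48,5.36,1020.50
G29,TNAU-HG-044,125.96,177.73,418.28,3.39,5.67,1048.48
G30,PAIYUR2,126.58,189.86,204.26,3.53,5.20,925.57
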