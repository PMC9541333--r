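wavelength_nm,value
400,0.130
420,0.085
440,0.065
460,0.055
480,0.045
500,0.038
520,0.032
540,0.027
560,0.023
580,0.020
600,0.018
650,0.014
700,0.012
750,0.0105
800,0.010
850,0.012
880,0.020
900,0.040
915,0.075
930,0.110
945,0.070
960,0.040
980,0.028
1000,0.025
1040,0.033
1100,0.045
1150,0.180
1190,0.600
1210,1.30
1230,0.70
1250,0.42
1300,0.26
1350,0.32
1390,0.60
1410,0.75
1450,0.85
1500,0.65
1550,0.58
1600,0.55
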