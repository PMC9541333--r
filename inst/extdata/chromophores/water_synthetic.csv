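wavelength_nm,value
400,0.00058
420,0.00046
440,0.00036
460,0.00031
480,0.00026
500,0.00025
520,0.00032
540,0.00045
560,0.00062
580,0.00093
600,0.0023
620,0.0028
640,0.0031
660,0.0036
680,0.0043
700,0.0060
720,0.0104
740,0.0236
750,0.0260
760,0.0270
780,0.0236
800,0.0204
820,0.0239
840,0.0312
860,0.0433
880,0.0556
900,0.0679
920,0.109
940,0.268
960,0.390
970,0.450
980,0.430
1000,0.363
1040,0.160
1080,0.120
1100,0.170
1130,0.380
1160,0.700
1180,0.950
1200,1.04
1220,1.10
1250,0.90
1300,1.20
1350,3.30
1380,7.00
1400,12.0
1420,18.0
1440,26.0
1450,30.0
1470,28.0
1500,21.5
1550,10.5
1600,6.70
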