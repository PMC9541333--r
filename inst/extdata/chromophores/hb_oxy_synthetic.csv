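wavelength_nm,value
400,266232
405,319616
410,466840
414,480000
420,233536
430,102580
440,65972
450,62816
460,44496
470,33209
480,26629
490,23684
500,20932
510,20035
520,24202
530,39956
540,53236
550,43016
555,36000
560,32613
565,36000
570,44940
577,56000
580,50104
590,14677
600,3200
610,1506
620,942
630,610
640,442
650,368
660,319
670,294
680,277
690,276
700,290
710,314
720,348
730,410
740,446
750,518
760,586
770,650
780,710
790,766
800,816
820,916
840,1022
860,1080
880,1154
900,1198
920,1232
940,1214
960,1166
980,1108
1000,1050
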