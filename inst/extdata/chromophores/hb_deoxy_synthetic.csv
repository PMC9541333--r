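wavelength_nm,value
400,223296
410,300000
420,410000
430,528600
435,500000
440,270000
450,103292
460,70000
470,50000
480,30000
500,20862
520,25773
530,35000
540,46592
550,52100
555,53412
560,53788
570,45000
580,33000
590,22000
600,14677
610,10500
620,9443
630,8500
640,5500
650,3750
660,3227
670,2900
680,2407
690,2100
700,1794
710,1600
720,1450
730,1350
740,1400
750,1550
760,1674
770,1480
780,1345
790,1050
800,820
810,780
820,745
840,700
860,685
880,700
900,752
920,790
940,820
960,800
980,740
1000,690
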