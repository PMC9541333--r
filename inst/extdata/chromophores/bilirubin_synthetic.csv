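wavelength_nm,value
400,27000
410,31000
420,38000
430,45000
440,51500
450,54800
455,55300
460,53500
470,47000
480,36500
490,25000
500,15500
510,9000
520,4800
530,2400
540,1100
550,450
560,170
570,60
580,20
590,7
600,2.5
620,0.4
650,0.05
700,0
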