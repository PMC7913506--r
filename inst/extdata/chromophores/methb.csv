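# methemoglobin (metHb, aquomet form, neutral pH) molar extinction / absorption tabulation
# units: L mol^-1 cm^-1
# source: compiled from standard literature tabulations of methemoglobin molar extinction; interpolated to a 10 nm grid (approximate)
# grid: 400-700 nm, 10 nm step
wavelength_nm,epsilon
400, 150000
410, 120000
420,  80000
430,  40000
440,  20000
450,  12000
460,   9500
470,   8700
480,   8600
490,   8900
500,   9150
510,   8800
520,   8200
530,   7600
540,   7100
550,   6400
560,   5500
570,   4800
580,   4100
590,   3700
600,   3300
610,   3300
620,   3500
630,   3900
640,   3300
650,   2200
660,   1500
670,   1100
680,    900
690,    800
700,    750
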