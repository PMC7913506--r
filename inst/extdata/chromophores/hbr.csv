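# deoxygenated hemoglobin (HbR) molar extinction / absorption tabulation
# units: L mol^-1 cm^-1
# source: compiled from standard literature tabulations of deoxyhemoglobin molar extinction; interpolated to a 10 nm grid (approximate)
# grid: 400-700 nm, 10 nm step
wavelength_nm,epsilon
400, 223296
410, 303956
420, 413280
430, 533128
440, 213240
450,  89400
460,  57080
470,  40344
480,  31500
490,  27000
500,  20862
510,  25773
520,  26600
530,  39036
540,  46592
550,  53412
560,  53290
570,  44000
580,  26000
590,  17000
600,  14677
610,   9500
620,   7200
630,   5149
640,   4345
650,   3750
660,   3227
670,   2795
680,   2407
690,   2051
700,   1794
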