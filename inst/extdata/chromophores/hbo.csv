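# oxygenated hemoglobin (HbO) molar extinction / absorption tabulation
# units: L mol^-1 cm^-1
# source: compiled from standard literature tabulations of oxyhemoglobin molar extinction; interpolated to a 10 nm grid (approximate)
# grid: 400-700 nm, 10 nm step
wavelength_nm,epsilon
400, 266232
410, 466840
420, 480360
430, 246072
440, 102580
450,  62816
460,  44480
470,  33209
480,  26629
490,  23684
500,  20932
510,  20035
520,  28324
530,  39956
540,  53236
550,  43016
560,  32613
570,  44496
580,  50104
590,  14400
600,   3200
610,   1506
620,    942
630,    610
640,    442
650,    368
660,    320
670,    294
680,    278
690,    276
700,    290
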