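# melanin (melanosome interior) molar extinction / absorption tabulation
# units: mm^-1 at unit melanosome volume fraction
# source: power-law approximation mu_a = 1.70e11 * lambda_nm^-3.48 mm^-1 (standard skin-optics melanosome model)
# grid: 400-700 nm, 10 nm step
wavelength_nm,epsilon
400, 149.72
410,137.392
420, 126.34
430,116.407
440,107.457
450,99.3732
460,92.0559
470,85.4178
480,79.3833
490,73.8867
500,68.8705
510,64.2843
520,60.0838
530,56.2301
540,52.6888
550,49.4296
560,46.4253
570, 43.652
580,41.0884
590,38.7154
600,36.5159
610,34.4747
620,32.5781
630,30.8137
640,29.1704
650,27.6382
660,26.2081
670,24.8719
680,23.6221
690, 22.452
700,21.3554
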