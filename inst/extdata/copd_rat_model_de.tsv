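gene	fc	t	p
Dhx16	0.530623	-3.72567	0.003938
Upf2	1.039416	3.475603	0.005965
Uqcrc2	1.015124	3.212685	0.00929
Rhobtb3	0.884189	-3.09422	0.011362
Znhit3	1.012759	3.046952	0.012316
Denr	1.013586	3.017057	0.01296
Notch3	0.975045	-2.97443	0.01394
Sdhc	0.984546	-2.5892	0.026987
Dyrk2	0.923138	-2.53068	0.029836
Sec61a1	1.039209	2.52876	0.029934
Hmmr	0.688459	-2.48504	0.032263
Exosc7	0.943282	-2.48184	0.032441
Sh3gl3	0.718159	-2.42208	0.035933
Noa1	0.971469	-2.28776	0.045186
Trrap	1.043465	2.252802	0.047951
Plk4	0.857672	-2.24158	0.048873
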