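# Oxyhemoglobin absorption coefficient at average whole-blood concentration
# c(HbT) = 150 g/l, molar mass 64500 g/mol: mu_a = ln(10) * eps * 150/64500,
# eps from a standard compiled molar extinction table (cm^-1 / (mol/l)).
# columns: wavelength_nm  mu_a_per_cm
660	1.714
680	2.175
700	1.553
720	1.901
740	2.389
760	3.138
780	3.803
800	4.370
820	4.906
840	5.474
860	5.849
880	6.181
900	6.416
920	6.502
940	6.502
960	6.406
980	6.041
1000	5.624
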