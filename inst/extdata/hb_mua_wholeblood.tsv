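# Deoxyhemoglobin absorption coefficient at average whole-blood concentration
# c(HbT) = 150 g/l, molar mass 64500 g/mol: mu_a = ln(10) * eps * 150/64500,
# eps from a standard compiled molar extinction table (cm^-1 / (mol/l)).
# columns: wavelength_nm  mu_a_per_cm
660	17.283
680	12.892
700	9.609
720	6.695
740	6.695
760	8.295
780	5.760
800	4.081
820	3.707
840	3.712
860	3.889
880	4.081
900	4.274
920	4.451
940	5.474
960	6.154
980	6.052
1000	5.249
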