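# Pure water absorption coefficient, near-infrared window, from standard
# literature compilations (interpolated to a 20 nm grid).
# columns: wavelength_nm  mu_a_per_cm
660	0.0036
680	0.0050
700	0.0060
720	0.0110
740	0.0270
760	0.0260
780	0.0235
800	0.0220
820	0.0280
840	0.0360
860	0.0450
880	0.0560
900	0.0680
920	0.1150
940	0.2700
960	0.4300
980	0.4300
1000	0.3600
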