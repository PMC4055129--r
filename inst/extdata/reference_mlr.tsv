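term	coefficient
(Intercept)	31.623
HBD_Count	2.5173
Num_RotatableBonds	-0.47471
CHI_V_1	-1.7664
IAC_Mean	-12.997
JX	-45.669
JY	36.62
SC_3_C	0.11612
Jurs_FNSA_1	18.941
Jurs_RPCS	-4.8012
Jurs_SASA	0.029451
Shadow_Xlength	-0.084377
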