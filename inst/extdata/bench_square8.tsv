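id	notation	length	e_star	e_ma	g_c	note
1	PH2PHP3HP2HP5H	18	-9	-9	98
2	HPHP3H3P4H2P2H	18	-8	-8	361
3	2H5P2H3PH3PHP	18	-4	-7	54	disputed: reported search value contradicts the reference optimum -4; excluded from checks
4	HPH2P2HPH2PHP2H2PHPH	20	-9	-9	342
5	3H2P2(HP)H2P2(HP)H2PH	20	-10	-9	400
6	2H2P6(H2P)2H	24	-9	-9	249
7	2PH2P3(2H4P)2H	25	-8	-8	301
8	3P2H2P2H5P7H2P2H4P2H2PH2P	36	-14	-14	435	sign typo in source report (printed 14); stored as -14
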