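id	e_star	e_r	e_p	h_pct	c_r	c_p
1	-9	-3	-5	57	33.4	55.6
2	-8	-4	-7	61	50	85.7
3	-4	-1	-3	33	25	75
4	-9	-2	-7	50	22.3	77.8
5	-9	-3	-8	50	33.4	88.9
6	-9	-2	-6	42	22.3	66.7
7	-8	-2	-5	36	25	64.3
8	-14	-4	-8	44	28.6	57.2
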