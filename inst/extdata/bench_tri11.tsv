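id	length	notation	e_hga	e_ersga	e_hhga	e_ts	e_cma	e_ossga	e_ma	note
B1	20	(HP)^2PH(HP)^2(PH)^2HP(PH)^2	-15	-15	-15	-15	-15	-15	-17
B2	24	H^2P^2(HP^2)^6H^2	-13	-14	-14	-17	-17	-17	-15
B3	25	P^2HP^2(H^2P^4)^3H^2	-10	-11	-11	-12	-12	-12	-14
B4	36	P(P^2H^2)^2P^5H^5(H^2P^2)^2P^2H(HP^2)^2	-19	-22	-22	-24	-24	-24	-28
B5	48	P^2H(P^2H^2)^2P^5H^10P^6(H^2P^2)^2HP^2H^5	-32	-34	-34	-40	-40	-43	-45
B6	50	H^2(PH)^3PH^4PH(P^3H)^2P^4(HP^3)^2HPH^4(PH)^3PH^2	-23	-32	-32	NA	-41	-41	-38
B7	60	P(PH^3)^2H^5P^3H^10PHP^3H^12P^4H^6PH^2PHP	-46	-62	-62	-70	-70	-70	-90
B8	64	H^12(PH)^2((P^2H^2)^2P^2H)^3(PH)^2H^11	-46	-51	-51	-50	-75	-74	-76
B9	85	H^4P^4H^12P^6H^12P^3H^12P^3H^12P^3HP^2(H^2P^2)^2HPH	NA	NA	NA	NA	NA	NA	-115	notation corrected from the source benchmark suite; the source article's printout drops one run and expands to 84
B10	100	P^6HPH^2P^5H^3P^5HPH^2P^4H^2P^2H^2P^5HPH^10PH^2PH^7P^11H^7P^2HPH^3P^6HPH^2	NA	NA	NA	NA	NA	NA	-70
B11	100	P^3H^2P^2H^4P^2H^3(PH^2)^2PH^4P^8H^6P^2H^6P^9HPH^2P^11H^2P^3HPH^2PHP^2HPH^3P^6H^3	NA	NA	NA	NA	NA	NA	-72
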