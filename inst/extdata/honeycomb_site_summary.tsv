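site	n	n_alleles	n_alleles_sd	theta	theta_sd	pi	he	he_sd	ho	ho_sd
Northern Irish Sea	6	2.50	0.50	0.28	0.14	132.56	0.53	0.34	0.14	0.19
North Atlantic	8	2.45	0.50	0.15	0.08	73.08	0.50	0.36	0.11	0.16
Southern Irish Sea	9	2.54	0.50	0.26	0.13	126.36	0.53	0.28	0.01	0.15
English Channel	11	2.49	0.50	0.29	0.14	140.50	0.49	0.33	0.09	0.15
Bay of Biscay	12	2.59	0.49	0.28	0.14	133.63	0.51	0.32	0.11	0.15
Tyrrhenian Sea	7	2.23	0.42	0.22	0.11	106.08	0.45	0.36	0.08	0.19
Balearic Sea	4	2.36	0.48	0.29	0.16	141.43	0.58	0.31	0.11	0.15
Iberian Peninsula	5	2.23	0.42	0.26	0.14	123.47	0.50	0.34	0.09	0.20
North Africa	6	2.53	0.50	0.32	0.16	152.42	0.55	0.34	0.14	0.19
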