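site	Northern Irish Sea	North Atlantic	Southern Irish Sea	English Channel	Bay of Biscay	Tyrrhenian Sea	Balearic Sea	Iberian Peninsula	North Africa
Northern Irish Sea	NA	453	180	864	1286	4134	3075	1853	2447
North Atlantic	0.36	NA	612	994	1332	3998	2939	1715	2311
Southern Irish Sea	0.30	0.42	NA	768	1190	4041	2982	1760	2354
English Channel	0.23	0.43	0.25	NA	834	3742	2683	1461	2056
Bay of Biscay	0.18	0.31	0.25	0.20	NA	3390	2331	1109	1703
Tyrrhenian Sea	0.35	0.58	0.31	0.20	0.31	NA	1177	2283	2150
Balearic Sea	0.22	0.31	0.25	0.22	0.22	0.34	NA	1224	1091
Iberian Peninsula	0.32	0.53	0.28	0.19	0.29	0.24	0.27	NA	597
North Africa	0.21	0.44	0.21	0.15	0.22	0.22	0.22	0.19	NA
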