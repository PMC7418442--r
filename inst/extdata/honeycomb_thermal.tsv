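block	parameter	Northern Irish Sea	North Atlantic	Southern Irish Sea	English Channel	Bay of Biscay	Iberian Peninsula
all	mean	10.82	11.62	11.93	14.21	16.67	16.10
all	max	37.85	39.37	34.78	41.54	42.13	35.48
all	min	-3.31	-5.62	-0.46	0.70	-2.46	3.32
all	range	41.16	44.99	35.24	40.84	44.59	32.16
all	sd	5.61	5.94	6.10	5.87	8.36	7.79
all	p95_p5	14.38	15.40	15.77	23.68	21.74	18.59
all	daily_range	7.51	7.11	6.77	8.15	8.28	8.28
all	daily_sd	5.50	5.50	4.51	5.76	5.30	5.42
water	mean	10.55	11.53	11.76	14.00	16.76	15.75
water	max	16.14	19.73	17.24	22.50	25.09	21.17
water	min	4.52	3.67	5.88	5.91	7.90	11.18
water	range	11.62	16.06	11.36	16.59	17.19	9.99
air	mean	11.06	11.84	12.04	14.59	16.58	16.59
air	max	37.76	36.93	34.53	41.54	40.74	34.49
air	min	-2.28	-4.73	0.00	0.70	-1.03	3.53
air	range	40.04	41.66	34.53	40.84	41.77	30.96
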