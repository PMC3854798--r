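trait	group	mean	sd	cv	median	h2	psd
Fat	fat	3.99	0.78	19.64	3.96	0.24	0.13
C6:0	fatty_acid	2.69	0.35	12.97	2.72	0.24	0.13
C8:0	fatty_acid	1.47	0.23	15.37	1.48	0.34	0.15
C10:0	fatty_acid	3.16	0.56	17.87	3.17	0.34	0.16
C12:0	fatty_acid	3.57	0.65	18.14	3.55	0.27	0.15
C13:0	fatty_acid	0.10	0.03	30.27	0.10	0.19	0.13
C14:0	fatty_acid	11.29	1.30	11.49	11.36	0.25	0.17
C15:0	fatty_acid	1.10	0.20	17.89	1.09	0.13	0.10
C16:0	fatty_acid	28.95	3.25	11.23	28.84	0.14	0.11
C17:0	fatty_acid	0.53	0.15	28.45	0.53	0.07	0.06
C18:0	fatty_acid	10.54	2.20	20.89	10.26	0.19	0.13
C14:1c9	fatty_acid	0.97	0.28	29.03	0.94	0.26	0.14
C16:1c9	fatty_acid	1.50	0.38	25.14	1.46	0.16	0.11
C18:1t11	fatty_acid	1.70	0.56	33.27	1.62	0.09	0.08
C18:1c9	fatty_acid	19.78	3.62	18.29	19.83	0.11	0.10
C18:2n6	fatty_acid	1.69	0.30	18.04	1.65	0.17	0.11
C18:3n3	fatty_acid	0.49	0.10	20.46	0.49	0.30	0.15
CLAc9t11	fatty_acid	0.63	0.16	26.22	0.60	0.19	0.13
SFA	group	63.40	3.81	6.00	63.51	0.09	0.08
UFA	group	26.76	3.87	14.46	26.54	0.33	0.19
MUFA	group	23.95	3.72	15.52	23.84	0.34	0.20
PUFA	group	2.81	0.45	15.93	2.76	0.28	0.15
C6toC14	group	22.18	2.80	12.63	22.26	0.28	0.17
C14index	index	0.08	0.02	25.02	0.08	0.31	0.16
C16index	index	0.05	0.01	21.53	0.05	0.19	0.12
C18index	index	0.65	0.08	12.24	0.66	0.35	0.19
CLAindex	index	0.28	0.06	22.21	0.27	0.16	0.12
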