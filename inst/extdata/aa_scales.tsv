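aa	A1	A2	A3	A4	A5	A6	A7	A8	A9	A10	A11	A12	A13	A14	A15	A16	A17	A18	A19	A20	A21	A22	A23	A24	A25	A26	A27	A28
A	1.8	0.44	0.61	0.1	5.33	0.39	1.94	-0.5	12.97	0.31	1.36	1.15	0.5	0.3	0.38	0.74	0.616	-0.4	0.62	0.36	0	0	6.6	4.34	86.6	11.5	8.1	100
C	2.5	0.58	0.36	-1.42	7.93	0.25	-1.24	-1	14.63	1.54	1.27	-1.2	0	0.9	0.5	0.91	0.68	0.17	0.29	0.35	2.75	1.48	0.9	35.77	132.3	13.46	5.5	20
D	-3.5	-0.31	0.61	0.78	3.59	-3.81	-10.95	3	10.85	-0.77	0.11	0.65	0	-0.6	0.15	0.62	0.028	-1.31	-0.9	0.51	1.38	49.7	7.7	12	97.8	11.68	13	106
E	-3.5	-0.34	0.51	0.83	3.65	-2.91	-10.2	3	11.89	-0.64	0.25	-0.71	0	-0.7	0.18	0.62	0.043	-1.22	-0.74	0.5	0.92	49.9	5.7	17.26	113.9	13.57	12.3	102
F	2.8	2.44	-1.52	-2.12	9.03	2.27	-0.76	-2.5	14	1.79	1.57	-1.41	2.5	0.5	0.5	0.88	1	1.92	1.19	0.31	0	0.35	2.4	29.4	194.1	19.8	5.2	41
G	-0.4	0	0.81	0.33	4.48	0	2.39	0	12.43	0	1.09	-1.84	0	0.3	0.36	0.72	0.501	-0.67	0.48	0.54	0.74	0	6.7	0	62.9	3.4	9	49
H	-3.2	-0.01	0.69	-0.5	5.1	-0.64	-10.27	-0.5	12.16	0.13	0.68	3.12	0.5	-0.1	0.17	0.78	0.165	-0.64	-0.4	0.32	0.58	51.6	2.5	21.81	155.8	13.69	10.4	66
I	4.5	2.46	-1.45	-1.13	8.83	1.82	2.15	-1.8	15.67	1.8	1.44	-2.92	1.8	0.7	0.6	0.88	0.943	1.25	1.38	0.46	0	0.13	2.8	19.06	158	21.4	5.2	96
K	-3.9	-2.45	0.46	1.4	2.95	-2.77	-9.52	3	11.36	-0.99	0.09	2.06	0	-1.8	0.03	0.52	0.283	-0.67	-1.5	0.47	0.33	49.5	10.3	21.29	115.5	15.71	11.3	56
L	3.8	2.32	-1.65	-1.18	8.47	1.82	2.28	-1.8	14.9	1.7	1.47	0.75	1.8	0.5	0.45	0.85	0.943	1.22	1.06	0.37	0	0.13	4.8	18.78	164.1	21.4	4.9	40
M	1.9	1.68	-0.66	-1.59	8.95	0.96	-1.48	-1.3	14.39	1.23	1.42	-3.85	1.3	0.4	0.4	0.85	0.738	1.02	0.64	0.3	0	1.43	1	21.64	172.9	16.25	5.7	94
N	-3.5	-1.32	0.89	0.48	3.71	-1.91	-9.68	0.2	11.42	-0.6	0.33	-0.77	0	-0.5	0.12	0.63	0.236	-0.92	-0.78	0.46	1.33	3.38	6.7	13.28	103.3	12.82	11.6	134
P	-1.6	1.29	-0.17	0.73	3.87	0.99	0	0	11.37	0.72	0.54	-0.53	1.4	-0.3	0.18	0.64	0.711	-0.49	0.12	0.51	0.39	1.58	4.8	10.93	92.9	17.43	8	56
Q	-3.5	-0.71	0.97	0.95	3.87	-1.3	-9.38	0.2	11.76	-0.22	0.33	-0.11	0	-0.7	0.07	0.62	0.251	-0.91	-0.85	0.49	0.89	3.53	5.2	17.56	119.2	14.45	10.5	93
R	-4.5	-2.42	0.69	1.91	4.18	-3.95	-19.92	3	11.72	-1.01	0.15	0.58	0	-1.4	0.01	0.64	0	-0.59	-2.53	0.53	0.65	52	4.5	26.66	162.2	14.28	10.5	65
S	-0.8	-0.84	0.42	0.52	4.09	-1.24	-5.06	0.3	11.23	-0.04	0.97	-0.26	0	-0.1	0.22	0.66	0.359	-0.55	-0.18	0.51	1.42	1.67	9.4	6.35	85.6	9.47	9.2	120
T	-0.7	-0.41	0.29	0.07	4.49	-1	-4.88	-0.4	11.69	0.26	1.08	-0.45	0.4	-0.2	0.23	0.7	0.45	-0.28	-0.05	0.44	0.71	1.66	7	11.01	106.5	15.77	8.6	97
V	4.2	1.73	-0.75	-1.27	7.63	1.3	1.99	-1.5	15.71	1.22	1.37	-0.13	1.5	0.6	0.54	0.86	0.825	0.91	1.08	0.39	0	0.13	4.5	13.92	141	21.57	5.9	74
W	-0.9	3.07	-1.2	-0.51	7.66	2.13	-5.88	-3.4	13.93	2.25	1	-1.14	3.4	0.3	0.27	0.85	0.878	0.5	0.81	0.31	0.13	2.1	1.4	42.53	224.6	21.67	5.4	18
Y	-1.3	1.31	-1.43	-0.21	5.89	1.47	-6.11	-2.3	13.42	0.96	0.83	0.13	2.3	-0.4	0.15	0.76	0.88	1.67	0.26	0.42	0.2	1.61	5.1	31.53	177.7	18.03	6.2	41
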