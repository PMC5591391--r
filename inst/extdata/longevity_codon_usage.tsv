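# Mean codon frequencies (per mil) in the 13 mitogenome-encoded protein genes
# of three cohorts of Japanese males: 97 healthy controls, 112 semi-supercentenarians,
# 96 centenarians. Transcribed from the published cohort comparison table;
# cda column is the published base-scheme codon directional asymmetry score.
codon	cda	control	supercentenarian	centenarian
AAA	0	22.37	22.4	22.39
AAC	1	34.72	34.74	34.72
AAG	0.5	2.63	2.61	2.61
AAU	1	8.38	8.39	8.41
ACA	0	34.8	34.78	34.77
ACC	-1	40.44	40.45	40.36
ACG	0.5	2.57	2.58	2.58
ACU	-0.5	13.41	13.39	13.43
AGA	0	0.3	0.29	0.3
AGC	0.5	10.26	10.27	10.29
AGG	-0.5	0.3	0.3	0.3
AGU	0.5	3.7	3.69	3.69
AUA	0	43.77	43.81	43.82
AUC	-0.5	51.34	51.3	51.25
AUG	-0.5	10.72	10.74	10.73
AUU	-1	33.06	33.03	33.07
CAA	-1	21.61	21.61	21.59
CAC	0	20.8	20.8	20.79
CAG	-0.5	2.08	2.09	2.1
CAU	0.5	4.71	4.71	4.71
CCA	1	13.71	13.71	13.72
CCC	0	31.39	31.43	31.42
CCG	1	1.78	1.78	1.78
CCU	0.5	10.7	10.66	10.68
CGA	-0.5	7.4	7.4	7.4
CGC	0	6.8	6.8	6.8
CGG	-1	0.5	0.5	0.5
CGU	-0.5	1.8	1.8	1.8
CUA	0.5	72.88	72.87	72.9
CUC	0	43.89	43.88	43.89
CUG	0.5	11.74	11.78	11.79
CUU	-0.5	17.02	17.03	17
GAA	-0.5	16.87	16.85	16.86
GAC	0.5	13.43	13.38	13.38
GAG	0	6.23	6.25	6.24
GAU	0.5	3.89	3.92	3.93
GCA	-0.5	21.6	21.58	21.6
GCC	-1	32.55	32.56	32.6
GCG	0	2.08	2.09	2.08
GCU	-0.5	11.73	11.73	11.74
GGA	0.5	18	18.02	18.03
GGC	1	22.88	22.87	22.85
GGG	0	8.55	8.52	8.51
GGU	1	6.3	6.32	6.33
GUA	0.5	18.39	18.4	18.36
GUC	-0.5	12.61	12.64	12.68
GUG	0	4.71	4.71	4.73
GUU	-1	8.19	8.19	8.18
UAA	-1	2.09	2.09	2.1
UAC	-0.5	23.39	23.35	23.35
UAG	-0.5	0.81	0.81	0.8
UAU	0	12.11	12.13	12.15
UCA	0.5	21.81	21.81	21.8
UCC	-0.5	25.99	25.99	26
UCG	0.5	1.8	1.79	1.8
UCU	0	8.42	8.42	8.41
UGA	-0.5	24.48	24.46	24.42
UGC	0.5	4.5	4.5	4.5
UGG	-1	2.91	2.92	2.97
UGU	0	1.3	1.3	1.31
UUA	1	19.07	19.04	19.01
UUC	0.5	36.59	36.61	36.6
UUG	1	4.59	4.57	4.57
UUU	0	20.34	20.32	20.34
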