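# scale: all_beta
# provenance: Conformational preference for all beta-strands (Lifson-Sander, 1979) -- Lifson, S. and Sander, C. Antiparallel and parallel beta-strands differ in amino acid residue preference Nature 282, 109-111 (1979)
# aaindex: LIFS790101
residue	value
Ala	0.92
Arg	0.93
Asn	0.6
Asp	0.48
Cys	1.16
Gln	0.95
Glu	0.61
Gly	0.61
His	0.93
Ile	1.81
Leu	1.3
Lys	0.7
Met	1.19
Phe	1.25
Pro	0.4
Ser	0.82
Thr	1.12
Trp	1.54
Tyr	1.53
Val	1.81
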