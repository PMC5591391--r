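# scale: parallel_beta
# provenance: Conformational preference for parallel beta-strands (Lifson-Sander, 1979) -- Lifson, S. and Sander, C. Antiparallel and parallel beta-strands differ in amino acid residue preference Nature 282, 109-111 (1979)
# aaindex: LIFS790102
residue	value
Ala	1
Arg	0.68
Asn	0.54
Asp	0.5
Cys	0.91
Gln	0.28
Glu	0.59
Gly	0.79
His	0.38
Ile	2.6
Leu	1.42
Lys	0.59
Met	1.49
Phe	1.3
Pro	0.35
Ser	0.7
Thr	0.59
Trp	0.89
Tyr	1.08
Val	2.63
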