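# scale: antiparallel_beta
# provenance: Conformational preference for antiparallel beta-strands (Lifson-Sander, 1979) -- Lifson, S. and Sander, C. Antiparallel and parallel beta-strands differ in amino acid residue preference Nature 282, 109-111 (1979)
# aaindex: LIFS790103
residue	value
Ala	0.9
Arg	1.02
Asn	0.62
Asp	0.47
Cys	1.24
Gln	1.18
Glu	0.62
Gly	0.56
His	1.12
Ile	1.54
Leu	1.26
Lys	0.74
Met	1.09
Phe	1.23
Pro	0.42
Ser	0.87
Thr	1.3
Trp	1.75
Tyr	1.68
Val	1.53
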