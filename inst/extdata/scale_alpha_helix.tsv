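# scale: alpha_helix
# provenance: Normalized frequency of alpha-helix (Chou-Fasman, 1978b) -- Chou, P.Y. and Fasman, G.D. Prediction of the secondary structure of proteins from their amino acid sequence Adv. Enzymol. 47, 45-148 (1978)
# aaindex: CHOP780201
residue	value
Ala	1.42
Arg	0.98
Asn	0.67
Asp	1.01
Cys	0.7
Gln	1.11
Glu	1.51
Gly	0.57
His	1
Ile	1.08
Leu	1.21
Lys	1.16
Met	1.45
Phe	1.13
Pro	0.57
Ser	0.77
Thr	0.83
Trp	1.08
Tyr	0.69
Val	1.06
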