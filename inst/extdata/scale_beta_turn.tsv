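# scale: beta_turn
# provenance: Normalized frequency of beta-turn (Chou-Fasman, 1978a) -- Chou, P.Y. and Fasman, G.D. Empirical predictions of protein conformation Ann. Rev. Biochem. 47, 251-276 (1978)
# aaindex: CHOP780101
residue	value
Ala	0.66
Arg	0.95
Asn	1.56
Asp	1.46
Cys	1.19
Gln	0.98
Glu	0.74
Gly	1.56
His	0.95
Ile	0.47
Leu	0.59
Lys	1.01
Met	0.6
Phe	0.6
Pro	1.52
Ser	1.43
Thr	0.96
Trp	0.96
Tyr	1.14
Val	0.5
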