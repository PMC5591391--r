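# natural circular code X0 (20 trinucleotides, RNA form)
AAC
AAU
ACC
AUC
AUU
CAG
CUC
CUG
GAA
GAC
GAG
GAU
GCC
GGC
GGU
GUA
GUC
GUU
UAC
UUC
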