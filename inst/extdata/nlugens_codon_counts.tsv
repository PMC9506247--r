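codon	aa	count
UUU	Phe	25.5
UUC	Phe	4.5
UUA	Leu	25.7
UUG	Leu	3.5
CUU	Leu	4.8
CUC	Leu	0.8
CUA	Leu	4.5
CUG	Leu	0.5
AUU	Ile	26.1
AUC	Ile	3.5
AUA	Met	16.5
AUG	Met	2.7
GUU	Val	4.8
GUC	Val	0.6
GUA	Val	4.5
GUG	Val	0.6
UCU	Ser	8.5
UCC	Ser	2.5
UCA	Ser	7.3
UCG	Ser	0.5
CCU	Pro	3.4
CCC	Pro	2.9
CCA	Pro	3.4
CCG	Pro	0.2
ACU	Thr	4.5
ACC	Thr	2.2
ACA	Thr	4.1
ACG	Thr	0.2
GCU	Ala	2.8
GCC	Ala	1.0
GCA	Ala	2.0
GCG	Ala	0.1
UAU	Tyr	9.6
UAC	Tyr	2.0
UAA	Stop	0.0
UAG	Stop	0.0
CAU	His	3.5
CAC	His	1.5
CAA	Gln	3.1
CAG	Gln	0.6
AAU	Asn	11.2
AAC	Asn	2.3
AAA	Lys	8.9
AAG	Lys	1.5
GAU	Asp	3.3
GAC	Asp	1.2
GAA	Glu	5.5
GAG	Glu	0.6
UGU	Cys	3.0
UGC	Cys	0.2
UGA	Trp	5.2
UGG	Trp	0.8
CGU	Arg	1.1
CGC	Arg	0.1
CGA	Arg	1.8
CGG	Arg	0.4
AGU	Ser	3.9
AGC	Ser	0.5
AGA	Ser	5.9
AGG	Ser	0.8
GGU	Gly	4.8
GGC	Gly	0.5
GGA	Gly	5.1
GGG	Gly	2.1
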