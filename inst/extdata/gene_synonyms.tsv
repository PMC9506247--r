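synonym	canonical
COX1	cox1
COI	cox1
CO1	cox1
COX2	cox2
COII	cox2
CO2	cox2
COX3	cox3
COIII	cox3
CO3	cox3
ATP6	atp6
ATPASE6	atp6
ATP8	atp8
ATPASE8	atp8
ND1	nad1
ND2	nad2
ND3	nad3
ND4	nad4
ND4L	nad4l
NAD4L	nad4l
ND5	nad5
ND6	nad6
COB	cytb
CYTB	cytb
CYB	cytb
CB	cytb
12S	rrnS
12S-RRNA	rrnS
SRRNA	rrnS
RRN12	rrnS
16S	rrnL
16S-RRNA	rrnL
LRRNA	rrnL
RRN16	rrnL
D-LOOP	CR
AT-RICH	CR
CONTROL-REGION	CR
CONTROL_REGION	CR
TRNL-UUR	trnL2
TRNL-CUN	trnL1
TRNS-UCN	trnS2
TRNS-AGN	trnS1
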