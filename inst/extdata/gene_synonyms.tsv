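synonym	canonical
ND1	nad1
ND2	nad2
ND3	nad3
ND4	nad4
ND4L	nad4l
ND5	nad5
ND6	nad6
NAD1	nad1
NAD2	nad2
NAD3	nad3
NAD4	nad4
NAD4L	nad4l
NAD5	nad5
NAD6	nad6
NADH1	nad1
NADH2	nad2
NADH3	nad3
NADH4	nad4
NADH4L	nad4l
NADH5	nad5
NADH6	nad6
NADH DEHYDROGENASE SUBUNIT 1	nad1
NADH DEHYDROGENASE SUBUNIT 2	nad2
NADH DEHYDROGENASE SUBUNIT 3	nad3
NADH DEHYDROGENASE SUBUNIT 4	nad4
NADH DEHYDROGENASE SUBUNIT 4L	nad4l
NADH DEHYDROGENASE SUBUNIT 5	nad5
NADH DEHYDROGENASE SUBUNIT 6	nad6
COI	cox1
COII	cox2
COIII	cox3
CO1	cox1
CO2	cox2
CO3	cox3
COX1	cox1
COX2	cox2
COX3	cox3
COXI	cox1
COXII	cox2
COXIII	cox3
CYTOCHROME C OXIDASE SUBUNIT I	cox1
CYTOCHROME C OXIDASE SUBUNIT II	cox2
CYTOCHROME C OXIDASE SUBUNIT III	cox3
CYTB	cob
CYB	cob
COB	cob
CYTOCHROME B	cob
ATP6	atp6
ATP8	atp8
ATPASE6	atp6
ATPASE8	atp8
ATP SYNTHASE F0 SUBUNIT 6	atp6
ATP SYNTHASE F0 SUBUNIT 8	atp8
12S	rrnS
12S RRNA	rrnS
12S RIBOSOMAL RNA	rrnS
RRN12	rrnS
S-RRNA	rrnS
SMALL SUBUNIT RIBOSOMAL RNA	rrnS
RRNS	rrnS
16S	rrnL
16S RRNA	rrnL
16S RIBOSOMAL RNA	rrnL
RRN16	rrnL
L-RRNA	rrnL
LARGE SUBUNIT RIBOSOMAL RNA	rrnL
RRNL	rrnL
D-LOOP	control_region
CONTROL REGION	control_region
A+T RICH REGION	control_region
AT-RICH REGION	control_region
PUTATIVE CONTROL REGION	control_region
TRNA	trnA
TRNR	trnR
TRNN	trnN
TRND	trnD
TRNC	trnC
TRNE	trnE
TRNQ	trnQ
TRNG	trnG
TRNH	trnH
TRNI	trnI
TRNL1	trnL1
TRNL2	trnL2
TRNK	trnK
TRNM	trnM
TRNF	trnF
TRNP	trnP
TRNS1	trnS1
TRNS2	trnS2
TRNT	trnT
TRNW	trnW
TRNY	trnY
TRNV	trnV
TRNA-ALA	trnA
TRNA-ARG	trnR
TRNA-ASN	trnN
TRNA-ASP	trnD
TRNA-CYS	trnC
TRNA-GLU	trnE
TRNA-GLN	trnQ
TRNA-GLY	trnG
TRNA-HIS	trnH
TRNA-ILE	trnI
TRNA-LEU	trnL2
TRNA-LEU(UUR)	trnL2
TRNA-LEU(CUN)	trnL1
TRNA-LEU(TAA)	trnL2
TRNA-LEU(TAG)	trnL1
TRNA-LYS	trnK
TRNA-MET	trnM
TRNA-PHE	trnF
TRNA-PRO	trnP
TRNA-SER	trnS2
TRNA-SER(AGN)	trnS1
TRNA-SER(UCN)	trnS2
TRNA-SER(GCT)	trnS1
TRNA-SER(TGA)	trnS2
TRNA-THR	trnT
TRNA-TRP	trnW
TRNA-TYR	trnY
TRNA-VAL	trnV
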