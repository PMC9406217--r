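compound	gene_id	log_fold_change	inhibitor_exists	inhibitor_is_antibody	secreted	recombinant_exists	activator_exists	is_growth_factor	is_ecm	known_or_contradictory
WAY 170523	MMP13	1.8	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
EED226	SUZ12	0.9	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
APE1 Inhibitor III	APEX1	1.1	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
Silibinin	TMEM167A	0.7	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
Recombinant Netrin	UNC5B	-1.2	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
CINPA 1	CXADR	1.4	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
BITC	AGPS	0.8	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
AMZ-30	PME1	1.3	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
FDI-6	FOXM1	2.1	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
CPI-637	EP300	0.6	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
Anti-Galectin-9 Antibody	LGALS9	1.0	TRUE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
Recombinant Sonic Hedgehog/Shh	HHIP	1.5	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
C5OH	S100P	1.9	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
Recombinant C1qTNF1	C1QTNF1	-0.8	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
Recombinant Angiopoietin-like 4	ANGPTL4	-1.6	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
Recombinant CXCL5/ENA-7	CXCL5	-1.1	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
Recombinant Semaphorin 3C	SEMA3C	-0.9	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
Recombinant LTBP1	LTBP1	-0.5	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE
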