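protein_name,gene_symbol,theoretical_mass_da,n_peptides,coverage_pct
High mobility group protein HMG-I/HMG-Y isoform a,AHCTF1,11669,2,29.2
Alpha-2-HS-glycoprotein,AHSG,39193,5,25
Anexin 2,ANXA2,38808,3,13.6
Cycle-like factor CLIF,ARNTL2,67908,1,2
Aspartyl beta-hydroxylase,ASPH,85959,1,3
Potassium-transporting ATPase alpha chain 1,ATP4A,114045,1,2
Putative uncharacterized protein C5orf27,C5ORF27,10849,1,14.58
Chromobox homolog 1,CBX1,21519,2,11.2
Chromobox homolog 3,CBX3,20997,2,15.2
Coiled-coil domain-containing protein 73,CCDC73,1079,1,2.78
Cardiomyopathy-associated protein 5,CMYA5,17545,1,0.9
"Damage-specific DNA-binding protein 1, 127kDa",DDB1,128086,1,1.4
Translation elongation factor 1-alpha,EEF1A1,35825,2,12
Eukaryotic translation elongation factor 2,EEF2,96246,1,2.9
Translation initiation factor eIF3 p40 subunit,EIF3H,40075,1,5
FtsJ3 protein,FTSJ3,84015,1,2
Gelsolin,GSN,31052,3,22.7
High mobility group AT-hook 1,HMGA1,34635,1,5.1
Heme oxygenase 1,HO-1,32798,5,25
Heat shock 27 kDa protein,HSPB1,22427,3,31.4
Junctional sarcoplasmic reticulum protein 1,JSRP1,36296,1,2
KH-type splicing regulatory protein,KHSRP,10362,1,24.4
Lasp-1,LASP1,30185,1,5
Matrin 3,MATR3,95078,2,5
Multiple epidermal growth factor-like domains protein 10,MEGF10,122121,1,2.11
Muskelin 1,MKLN1,84713,11,17
Kinesin-like protein KIF23,MKLP-1,98842,1,1.7
Interferon-induced Mx protein,MX1,75929,1,2
Nucleosome assembly protein 1-like 1,NAP1L1,45631,1,4.1
Nitric oxide-associated protein,NOA1,78409,1,4.44
Nucleophosmin 1,NPM1,3109,2,12.7
"5'-Nucleotidase, cytosolic II",NT5C2,65384,1,2
"Palmdelphin, isoform CRA_a",PALMD,53404,1,2
Programmed cell death 5 short isoform,PDCD5,4472,1,32
Peroxiredoxin 2,PDX2,22014,1,5
Purine-rich element binding protein A,PURA,35003,1,8.2
Retinoic acid-induced 14,RAI14,110617,1,1.5
Regulator of chromosome condensation,RCC1,44485,1,3.7
Replication protein A 70 kDa DNA-binding subunit,RPA1,68723,1,3.6
Ribosomal protein SA pseudogene 9,RPSA1,32947,1,9
s100 calcium- binding protein A6,S100A6BP,1023,1,8
"Splicing factor, arginine/serine-rich 3",SFRS3,19546,1,11.8
Signal-induced proliferation-associated 1-like protein 1,SIPA1L1,201102,1,1.25
K-Cl co-transporter KCC4,SLC12A7,120327,1,0.6
Isoform 4 of Spastin,SPAST,54385,1,7.23
Spermatogenesis-associated protein 7,SPATA7,8799,1,36.84
Sequestosome 1,SQSTM1,4837,1,4.5
RNA polymerase II transcription factor SIII subunit A3-like-2,TCEB3CL2,59735,1,3.48
Testis-derived transcript,TES,49789,1,3.1
Thyroid hormone receptor-associated protein 3,THRAP3,108686,1,1.9
Mitochondrial import inner membrane translocase subunit,TIMM44,15215,1,19.55
Tropomodulin 3,TMOD3,39727,2,9.7
DNA topoisomerase 1,TOP1,66890,2,5.3
Tripartite motif-containing 28,TRIM28,80621,6,18
"Zinc-finger CCCH-type, antiviral 1",ZC3HAV1,103135,3,7.3
Zinc-finger protein 589,ZNF589,40736,7,36
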