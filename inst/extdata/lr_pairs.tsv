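ligand	receptor	source
S100a6	Anxa2	celltalkdb
Cfh	Itgam	celltalkdb
Serpine2	Plaur	cellphonedb
Icam1	Itgav	cellchat
Icam1	Itgam	cellchat
Lrg1	Acvrl1	cellphonedb
Apoe	Lrp1	celltalkdb
Cxcl12	Cxcr4	cellchat
Ccl3	Ccr1	cellchat
Tnf	Tnfrsf1a	celltalkdb
Vegfa	Kdr	cellphonedb
Il1b	Il1r1	celltalkdb
Anxa1	Fpr1	cellchat
Mmp9	Cd44	celltalkdb
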