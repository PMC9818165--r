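celltype	gene
B	Cd79a
T	Cd3e
NK	Ncr1
NKT	Cd3e
NKT	Klrb1c
monocyte	Csf1r
macrophage	Mrc1
DC	Cd209a
neutrophil	Cxcr2
neutrophil	Ly6g
EC	Pecam1
EC	Cdh5
lymphatic_EC	Prox1
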