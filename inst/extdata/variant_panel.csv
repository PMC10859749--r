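rsid,locus,chrom_pos,major_allele,minor_allele,maf_combined,maf_rural,maf_urban,risk_is_major
rs10773003,SBNO1,12:123290580,G,A,0.11,0.10,0.12,FALSE
rs174546,FADS1,11:61802358,C,T,0.14,0.12,0.15,FALSE
rs17482753,LPL,8:19975135,G,T,0.08,0.08,0.07,TRUE
rs1800961,HNF4A,20:44413724,C,T,0.02,0.02,0.02,FALSE
rs2293889,TRPS1,8:115586972,G,T,0.34,0.31,0.36,FALSE
rs2814944,C6orf106,6:34585020,G,A,0.10,0.11,0.10,FALSE
rs4147536,ADH1B,4:99317955,G,T,0.22,0.20,0.24,TRUE
rs4148005,ABCA8,17:68886325,A,C,0.26,0.23,0.28,FALSE
rs4420638,APOC1,19:44919689,A,G,0.11,0.10,0.11,FALSE
rs660240,CELSR2,1:109275216,G,A,0.24,0.21,0.21,TRUE
rs737337,DOCK6,19:11236817,T,C,0.13,0.13,0.13,FALSE
rs7832643,PLEC,8:143948489,G,T,0.30,0.27,0.32,FALSE
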