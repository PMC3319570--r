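symbol	categories	aliases	phenotype_class	source
Amh	phenotype		sexual_differentiation	reconstructed
Ar	nuclear_receptor			paper_text
Ash2l	coregulator			paper_text
Bmp4	phenotype		embryonic_development	paper_text
Bmp7	phenotype		sexual_differentiation	paper_text
Bmp8a	phenotype		sexual_differentiation	paper_text
Carm1	methyltransferase	Prmt4		reconstructed
Cxxc1	methyltransferase			paper_text
Cyp11a1	phenotype		steroidogenesis	reconstructed
Cyp17a1	phenotype		steroidogenesis	paper_text
Dmrt1	phenotype		sexual_differentiation	paper_text
Dmrt2	phenotype		sexual_differentiation	paper_text
Dmrt3	phenotype		sexual_differentiation	paper_text
Dmrta1	phenotype		sexual_differentiation	paper_text
Dnmt1	methyltransferase			paper_text
Dnmt3b	methyltransferase			paper_text
Dot1l	methyltransferase			reconstructed
Dpy30	coregulator			paper_text
Ehmt1	methyltransferase	Glp		paper_text
Ehmt2	methyltransferase	G9a;Bat8		paper_text
Esr1	nuclear_receptor			paper_text
Esr2	nuclear_receptor			paper_text
Esrra	nuclear_receptor			reconstructed
Esrrb	nuclear_receptor			reconstructed
Esrrg	nuclear_receptor			reconstructed
Ezh1	methyltransferase			reconstructed
Ezh2	methyltransferase			reconstructed
Fgf9	phenotype		sexual_differentiation	paper_text
Hoxa10	phenotype		embryonic_development	paper_text
Hoxa11	phenotype		embryonic_development	paper_text
Hoxa4	phenotype		embryonic_development	paper_text
Hoxd3	phenotype		embryonic_development	paper_text
Hoxd8	phenotype		embryonic_development	paper_text
Hsd3b1	phenotype		steroidogenesis	reconstructed
Insl3	phenotype		sexual_differentiation	paper_text
Jag2	phenotype		sexual_differentiation	paper_text
Jmjd6	demethylase			reconstructed
Kdm1	demethylase	Aof2;Lsd1;Kdm1a		paper_text
Kdm1b	demethylase	Aof1		reconstructed
Kdm2a	demethylase	Fbxl11		reconstructed
Kdm2b	demethylase	Fbxl10		paper_text
Kdm3a	demethylase	Jmjd1a		paper_text
Kdm3b	demethylase	Jmjd1b		reconstructed
Kdm4a	demethylase	Jmjd2a		reconstructed
Kdm4b	demethylase	Jmjd2b		reconstructed
Kdm4c	demethylase	Jmjd2c		reconstructed
Kdm4d	demethylase			reconstructed
Kdm5a	demethylase	Jarid1a;Rbp2		reconstructed
Kdm5b	demethylase	Jarid1b;Plu1		paper_text
Kdm5c	demethylase	Jarid1c;Smcx		reconstructed
Kdm5d	demethylase	Jarid1d;Smcy		reconstructed
Kdm6a	demethylase	Utx		paper_text
Kdm6b	demethylase	Jmjd3		paper_text
Lep	phenotype		obesity	paper_text
Lepr	phenotype		obesity	paper_text
Leprot	phenotype		obesity	paper_text
Men1	methyltransferase;coregulator			paper_text
Mll1	methyltransferase	Kmt2a;Mll		paper_text
Mll2	methyltransferase	Kmt2b		reconstructed
Mll3	methyltransferase	Kmt2c		paper_text
Mll4	methyltransferase	Kmt2d		paper_text
Mll5	methyltransferase	Kmt2e		paper_text
Ncoa6	coregulator	Asc2;Trbp;Nrc		paper_text
Nr1d1	nuclear_receptor			reconstructed
Nr1d2	nuclear_receptor			paper_text
Nr1h2	nuclear_receptor			paper_text
Nr1h3	nuclear_receptor			reconstructed
Nr1h4	nuclear_receptor	Fxr		reconstructed
Nr1i2	nuclear_receptor	Pxr		reconstructed
Nr1i3	nuclear_receptor	Car		reconstructed
Nr2c1	nuclear_receptor	Tr2		paper_text
Nr2c2	nuclear_receptor	Tr4		paper_text
Nr2f1	nuclear_receptor			reconstructed
Nr2f2	nuclear_receptor			paper_text
Nr3c1	nuclear_receptor	Gr		paper_text
Nr3c2	nuclear_receptor	Mr		reconstructed
Nr4a1	nuclear_receptor			reconstructed
Nr4a2	nuclear_receptor			paper_text
Nr4a3	nuclear_receptor			reconstructed
Nr5a1	nuclear_receptor	Sf1		paper_text
Nr5a2	nuclear_receptor			paper_text
Nr6a1	nuclear_receptor			reconstructed
Nsd1	methyltransferase			reconstructed
Paxip1	methyltransferase;coregulator	Ptip		paper_text
Pgr	nuclear_receptor			reconstructed
Phf8	demethylase			reconstructed
Ppara	nuclear_receptor			reconstructed
Ppard	nuclear_receptor			paper_text
Pparg	nuclear_receptor			reconstructed
Prdm1	methyltransferase			reconstructed
Prdm16	methyltransferase			reconstructed
Prdm2	methyltransferase	Riz1		paper_text
Prdm4	methyltransferase			reconstructed
Prdm5	methyltransferase			reconstructed
Prdm6	methyltransferase			reconstructed
Prdm9	methyltransferase			reconstructed
Prm1	phenotype		spermatogenesis	paper_text
Prm2	phenotype		spermatogenesis	paper_text
Prmt1	methyltransferase			reconstructed
Prmt3	methyltransferase			reconstructed
Prmt5	methyltransferase			reconstructed
Prmt6	methyltransferase			reconstructed
Prmt7	methyltransferase			reconstructed
Rara	nuclear_receptor			paper_text
Rarb	nuclear_receptor			paper_text
Rarg	nuclear_receptor			reconstructed
Rbbp5	coregulator			paper_text
Rora	nuclear_receptor			paper_text
Rorb	nuclear_receptor			reconstructed
Rorc	nuclear_receptor			reconstructed
Rxra	nuclear_receptor			reconstructed
Rxrb	nuclear_receptor			reconstructed
Rxrg	nuclear_receptor			reconstructed
Setd1a	methyltransferase			reconstructed
Setd1b	methyltransferase			reconstructed
Setd2	methyltransferase			reconstructed
Setd7	methyltransferase			reconstructed
Setd8	methyltransferase	Kmt5a;PrSet7		reconstructed
Setdb1	methyltransferase	Eset		paper_text
Setdb2	methyltransferase			reconstructed
Shh	phenotype		sexual_differentiation	paper_text
Smyd1	methyltransferase			reconstructed
Smyd2	methyltransferase			reconstructed
Smyd3	methyltransferase			reconstructed
Sry	phenotype		sexual_differentiation	paper_text
Star	phenotype		steroidogenesis	paper_text
Suv39h1	methyltransferase			paper_text
Suv39h2	methyltransferase			reconstructed
Suv420h1	methyltransferase	Kmt5b		reconstructed
Suv420h2	methyltransferase	Kmt5c		paper_text
Thra	nuclear_receptor			reconstructed
Thrb	nuclear_receptor			reconstructed
Tnp1	phenotype		spermatogenesis	reconstructed
Vdr	nuclear_receptor			reconstructed
Wdr5	coregulator			paper_text
Whsc1	methyltransferase	Nsd2;Mmset		reconstructed
Whsc1l1	methyltransferase	Nsd3		reconstructed
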