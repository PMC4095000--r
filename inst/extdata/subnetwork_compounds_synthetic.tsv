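# Companion compound fixture for the synthetic subnetworks: herbal
# ingredients cover the apoptosis cascade (plus two VECC nodes), western
# drugs cover the VECC cascade (plus two apoptosis nodes).
compound_id	name	compound_class	target_id	link_type
ing_a	herbal ingredient a	herbal_ingredient	BCL2	direct
ing_a	herbal ingredient a	herbal_ingredient	BAX	direct
ing_a	herbal ingredient a	herbal_ingredient	CASP3	direct
ing_a	herbal ingredient a	herbal_ingredient	CASP9	direct
ing_a	herbal ingredient a	herbal_ingredient	P53	direct
ing_a	herbal ingredient a	herbal_ingredient	NOS3	direct
ing_b	herbal ingredient b	herbal_ingredient	JNK1	direct
ing_b	herbal ingredient b	herbal_ingredient	CYCS	direct
ing_b	herbal ingredient b	herbal_ingredient	NFKB1	direct
ing_b	herbal ingredient b	herbal_ingredient	ACTA2	direct
ing_c	herbal ingredient c	herbal_ingredient	PARP1	direct
ing_c	herbal ingredient c	herbal_ingredient	CASP8	direct
ing_c	herbal ingredient c	herbal_ingredient	FASR	direct
drug_a	western drug a	western_drug	ACE	direct
drug_a	western drug a	western_drug	REN	direct
drug_b	western drug b	western_drug	CACNA1C	direct
drug_b	western drug b	western_drug	EDNRA	direct
drug_b	western drug b	western_drug	NOS3	direct
drug_c	western drug c	western_drug	ADRB1	direct
drug_c	western drug c	western_drug	AGTR1	direct
drug_c	western drug c	western_drug	MYLK	direct
drug_c	western drug c	western_drug	TNFR1	direct
drug_c	western drug c	western_drug	NFKB1	direct
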