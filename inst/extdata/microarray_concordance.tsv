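accession	tissue	strain	treatment	same	opposite
GSE37537	whole body	-	dietary restriction	94	106
GSE26724	head/thorax	Canton-S	dietary restriction	61	33
GSE48145	whole body	-	ovoD mutant (sterile)	145	85
GSE48145	whole body	-	corpora allata knockout (CAKO)	45	37
GSE48145	whole body	-	ovoD mutant with CAKO	146	88
GSE26726	whole body	yw, w1118	dietary restriction (10 days)	112	75
GSE26726	whole body	yw, w1118	dietary restriction (40 days)	48	29
GSE26726	whole body	Canton-S	dietary restriction (10 days)	109	79
GSE26726	whole body	Canton-S	dietary restriction (40 days)	86	62
GSE26726	whole body	yw, w1118	p53 knockdown (10 days)	43	20
GSE26726	whole body	yw, w1118	sir2 overexpression (10 days)	91	40
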