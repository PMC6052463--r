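species	subgenus	species_group
Dvir	Drosophila	virilis-repleta
Dmoj	Drosophila	virilis-repleta
Dwil	Sophophora	willistoni
Dsal	Sophophora	saltans
Daus	Sophophora	saltans
Dana	Sophophora	melanogaster
Dbip	Sophophora	melanogaster
Dkik	Sophophora	melanogaster
Dbia	Sophophora	melanogaster
Dyak	Sophophora	melanogaster
Dere	Sophophora	melanogaster
Dmel	Sophophora	melanogaster
Dsim	Sophophora	melanogaster
Dsec	Sophophora	melanogaster
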