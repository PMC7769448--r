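group	section	n_obis	n_bold	n_sep
Arthropoda	Invertebrates	1363	403	35
Mollusca	Invertebrates	856	314	24
Cnidaria	Invertebrates	415	145	3
Annelida	Invertebrates	399	109	1
Echinodermata	Invertebrates	376	168	6
Porifera	Invertebrates	197	24	0
Bryozoa	Invertebrates	88	12	0
Platyhelminthes	Invertebrates	77	0	0
Nematoda	Invertebrates	33	1	0
Chaetognatha	Invertebrates	22	15	0
Nemertea	Invertebrates	21	4	2
Brachiopoda	Invertebrates	16	1	0
Xenacoelomorpha	Invertebrates	16	0	0
Tardigrada	Invertebrates	4	0	0
Hemichordata	Invertebrates	3	0	0
Acanthocephala	Invertebrates	3	0	0
Sipuncula	Invertebrates	1	0	0
Actinopterygii	Vertebrates	1439	978	155
Elasmobranchii	Vertebrates	129	102	18
Mammalia	Vertebrates	40	35	3
Reptilia	Vertebrates	6	6	2
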