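clade	repeat	n_species	note
Chordata	AACCCT	21	vertebrate TTAGGG equivalent; all chordate assemblies surveyed
Arthropoda	AACCT	308	most abundant canonical repeat across surveyed arthropod assemblies
Magnoliopsida	AAACCCT	19	flowering plants; classic plant-type telomeric repeat
Vespidae	AACCCAGACCC	4	long divergent repeat conserved across Vespa, Vespula, Dolichovespula, Ancistrocerus
Bombus	AACCCG	1	compound telomeric landscape; units interleaved along the array
Bombus	AACCT	1	compound telomeric landscape; units interleaved along the array
Bombus	AACCCT	1	compound telomeric landscape; units interleaved along the array
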