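taxon_id	parent_id	name	rank
ROOT	ROOT	root	root
K_ANI	ROOT	Metazoa	kingdom
K_PLA	ROOT	Viridiplantae	kingdom
F_CER	K_ANI	Cervidae	family
F_FAG	K_PLA	Fagaceae	family
F_HOM	K_ANI	Hominidae	family
T_DEER	F_CER	Cervus elaphus	species
T_CHST	F_FAG	Castanea sativa	species
T_KRT	F_HOM	Homo sapiens	species
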