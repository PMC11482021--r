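accession	taxon_id	category
DEER1	T_DEER	target
CHST1	T_CHST	target
KRT1	T_KRT	contaminant
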