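Sample	Sequence	Modifications	Proteins	Leading razor protein	MS/MS count
S_deer	AVLDEATMK		DEER1	DEER1	3
S_deer	GHSNTFELK	Deamidation (NQ)@3	DEER1	DEER1	2
S_deer	LNVQPYDTR		DEER1	DEER1	2
S_deer	AAGTK		DEER1	DEER1	1
S_deer	AVLDEATMKGHSNTFELKAAGTKSSLMDTYWK		DEER1	DEER1	1
S_deer	SSLMDTYWK		DEER1;KRT1	DEER1	2
S_deer	MMGYAVDLK		KRT1	KRT1	1
S_deer	LNVQPYDTR	Deamidation (NQ)@1;Deamidation (NQ)@3	DEER1	DEER1	1
W1	AVLDEATMK		DEER1	DEER1	1
W1	MMGYAVDLK		KRT1	KRT1	1
S_chest	QVNPLESGK		CHST1	CHST1	4
S_chest	TTIGFDHAK		CHST1	CHST1	2
S_chest	VVDSPNAGELTR	Deamidation (NQ)@5	CHST1	CHST1	1
S_chest	AVLDEATMK		DEER1	DEER1	2
S_chest	GHSNTFELK		DEER1	DEER1	1
S_chest	SSLMDTYWK		DEER1;KRT1	KRT1	1
S_chest	AAGTK		DEER1	DEER1	1
S_chest	TTIGFDHAKVVDSPNAGELTR		CHST1	CHST1	1
W2	QVNPLESGK		CHST1	CHST1	1
W2	GHSNTFELK		DEER1	DEER1	1
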