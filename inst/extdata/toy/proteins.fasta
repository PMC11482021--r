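>DEER1 synthetic deer muscle protein
AVLDEATMKGHSNTFELKAAGTKSSLMDTYWKLNVQPYDTR
>CHST1 synthetic chestnut seed protein
QVNPLESGKTTIGFDHAKVVDSPNAGELTR
>KRT1 synthetic keratin-like laboratory contaminant
MMGYAVDLKSSLMDTYWK
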