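>InA role=input;anchor=none;seed=20240101;version=1;synthetic=true
AAAGTGTATGGGGTCTA
>InB role=input;anchor=none;seed=20240101;version=1;synthetic=true
ACAAGGTAAACTCGGCAGGGCGGTTGGT
>InC role=input;anchor=none;seed=20240101;version=1;synthetic=true
CCCTATCACCATGACGACCT
>InD role=input;anchor=none;seed=20240101;version=1;synthetic=true
CTCCCCGATTGTCACATTGTGT
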