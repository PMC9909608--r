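cluster	label	gene	status
thalianol	A	AT5G47980	LOSS
thalianol	A	CYP705A5	LOSS
thalianol	A	CYP708A2	REF
thalianol	A	THAS1	LOSS
thalianol	A	AT5G47950	REF
thalianol	B	AT5G47980	LOSS
thalianol	B	CYP705A5	LOSS
thalianol	B	CYP708A2	LOSS
thalianol	B	THAS1	REF
thalianol	B	AT5G47950	REF
thalianol	C	AT5G47980	REF
thalianol	C	CYP705A5	REF
thalianol	C	CYP708A2	LOSS
thalianol	C	THAS1	REF
thalianol	C	AT5G47950	REF
thalianol	D	AT5G47980	REF
thalianol	D	CYP705A5	LOSS
thalianol	D	CYP708A2	LOSS
thalianol	D	THAS1	LOSS
thalianol	D	AT5G47950	REF
thalianol	E	AT5G47980	GAIN
thalianol	E	CYP705A5	REF
thalianol	E	CYP708A2	REF
thalianol	E	THAS1	REF
thalianol	E	AT5G47950	REF
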