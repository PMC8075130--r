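sample_id	group
F001	F
F002	F
F003	F
F004	F
F005	F
F006	F
NF001	NF
NF002	NF
NF003	NF
NF004	NF
NF005	NF
NF006	NF
NF007	NF
NF008	NF
NF009	NF
NF010	NF
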