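gene	start	end	strand	phase_offset	coding	wrap	note
ND4	10760	12136	+	0	TRUE	FALSE	ND4-like span trimmed to a full codon multiple (the genomic gene ends at 12137 with an incomplete stop completed by polyadenylation); position 11914 is codon 385, codon position 3
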