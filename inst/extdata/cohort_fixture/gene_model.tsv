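gene	start	end	strand	phase_offset	coding	wrap
CDS1	301	480	+	0	TRUE	FALSE
CDS2	500	580	-	0	TRUE	FALSE
TRN1	31	100	+	0	FALSE	FALSE
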