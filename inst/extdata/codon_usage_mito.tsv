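codon	per_thousand	note
ACA	32.7	human mitochondrion, frequency per thousand (Kazusa codon-usage snapshot)
ACG	2.6	human mitochondrion, frequency per thousand (Kazusa codon-usage snapshot)
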