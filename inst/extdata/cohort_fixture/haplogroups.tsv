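name	parent	variants
L0		
L1	L0	528C,122C
L2	L0	197G,161A
L3	L2	334A,387C
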