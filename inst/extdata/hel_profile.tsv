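# profile: HEL
[aberrations]
gene	kind	functional_call	magnitude
JAK2	mutation	auto	NA
TP53	mutation	auto	NA
CDKN2A	deletion	auto	NA
RB1	deletion	auto	NA
E2F1	amplification	auto	NA

[receptors]
receptor	status
IL6R	absent
TNFR	present
IFNGR	present
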