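# profile: SET2
[aberrations]
gene	kind	functional_call	magnitude
JAK2	mutation	auto	NA
RPTOR	mutation	auto	NA
TP53	mutation	auto	NA
CCNA2	mutation	auto	NA
NOTCH2	mutation	auto	NA
EGF	mutation	auto	NA
MAP2K1	mutation	auto	NA

[receptors]
receptor	status
IL6R	absent
TNFR	present
IFNGR	present
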