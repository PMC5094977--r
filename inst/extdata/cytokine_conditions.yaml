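IL6:
  IL6: 1.0
TNFA:
  TNFA: 1.0
IFNG:
  IFNG: 1.0
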