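- id: G6
  selectivity: JAK2>JAK3>>JAK1>>>TYK2
  fold_base: 5.0
  hill_h: 1.0
  K_primary: 1.0
- id: ABT737
  selectivity: BCL2>BCL2L1
  fold_base: 5.0
  hill_h: 1.0
  K_primary: 1.0
- id: JAKi
  selectivity: JAK2>JAK1>>TYK2
  fold_base: 5.0
  hill_h: 1.0
  K_primary: 1.0
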