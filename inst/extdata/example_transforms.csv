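lhs_smiles,rhs_smiles,support
[*]C,[*]CC,120
[*]C,[*]OC,95
[*]F,[*]Cl,80
[*]c1ccccc1,[*]c1ccncc1,60
[*]C(C)C,[*]C1CC1,45
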