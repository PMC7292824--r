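# common reactive / undesirable chemotypes (illustrative, not exhaustive)
c[N+](=O)[O-]   aromatic_nitro
[SX2H]          thiol
C(=O)Cl         acyl_chloride
[N;!R]=[N;!R]   acyclic_azo
O=C1OC(=O)C1    beta_lactone_like
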