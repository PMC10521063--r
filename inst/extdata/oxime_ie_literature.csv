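ligand,residue,IE
8a,Lys58,-17.3721
8a,Lys112,-15.6787
8b,Lys58,-18.8069
8b,Lys112,-19.6651
8d,Lys58,-14.5610
8d,Lys112,-18.2331
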