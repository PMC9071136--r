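id	smiles	role	source_note
triflusal	CC(=O)Oc1ccc(cc1C(O)=O)C(F)(F)F	positive_control	structure from standard registry
5-methoxysalicylic_acid	COc1ccc(O)c(c1)C(O)=O	test_compound	structure from standard registry
4-isopropylbenzoic_acid	CC(C)c1ccc(cc1)C(O)=O	negative_control	structure from standard registry
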