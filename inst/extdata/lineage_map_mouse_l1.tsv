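# mouse L1 subfamily prefix -> amplification lineage
# first matching prefix wins; order defines the lineage label order
L1ME	Eutherian
L1MB	Eutherian
L1_Mur	Rodent
Lx	Muridae
L1Md_	Mus
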