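compound	substrate_mz	product_mz
4-O-methylnorbelladine	274.30	272.30
4-O-methyl-N-methylnorbelladine	288.30	286.20
3-O-methylnorbelladine	274.30	272.30
3,4-O-dimethylnorbelladine	288.30	286.20
norbelladine	260.00	258.00
N-methylnorbelladine	274.30	272.30
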