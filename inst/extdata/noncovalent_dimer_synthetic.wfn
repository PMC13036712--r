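natoms 2
atom 8 0 0 0
atom 8 0 0 3.1
nbasis 2
basis 1 2
prim 1.6 0.5
prim 0.9 0.6
basis 2 2
prim 1.6 0.5
prim 0.9 0.6
nmo 2
mo 2 0.922781595891 0.000000000000
mo 2 0.000000000000 0.922781595891
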