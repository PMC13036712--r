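natoms 2
atom 1 0 0 0
atom 1 0 0 3
nbasis 2
basis 1 1
prim 1 1
basis 2 1
prim 0.5 1
nmo 2
mo 2 1 0
mo 2 0 1
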