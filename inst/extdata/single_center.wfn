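natoms 1
atom 1 0 0 0
nbasis 1
basis 1 1
prim 1 1
nmo 1
mo 2 1
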