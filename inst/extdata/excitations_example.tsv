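position	unit	f
334	nm	0.47
270	nm	0.18
221	nm	0.65
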