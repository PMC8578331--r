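pam	penalty
AGG	1
CGG	1
GGG	1
TGG	1
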