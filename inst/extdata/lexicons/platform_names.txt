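# Mutation-like microarray/platform names (seed list).
U133A
U133B
U95A
U95B
U219
HG-U133A
HG-U133B
HG-U95A
U133A2
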