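quantity	value
zygotes_2pn	1232
blastocysts	622
arrested	610
tested_blastocysts	612
tested_arrested	297
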