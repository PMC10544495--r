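category	arrested	blastocyst
Euploid	17	189
Meiotic only	66	228
Meiotic plus mitotic and/or seg	141	119
Mitotic only	32	29
Mitotic and/or seg	41	47
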