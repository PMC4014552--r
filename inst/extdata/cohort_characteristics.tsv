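characteristic	training_set	testing_set	entire_set
grade_II	32	31	63
grade_III	16	17	33
grade_IV	32	32	64
alive	41	51	92
deceased	39	29	68
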