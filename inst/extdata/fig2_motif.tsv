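# Worked-example motif pattern: a->b, a->c, b->d
a	b
a	c
b	d
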