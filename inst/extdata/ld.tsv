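id1	id2	r2
rs0001	rs0002	0.2
rs0001	rs0006	0.9
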