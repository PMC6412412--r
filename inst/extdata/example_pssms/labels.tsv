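id	label
pos0001	1
pos0002	1
neg0003	0
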