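stage	STn_positive	STn_negative
I	7	6
II	8	3
III	18	5
IV	1	0
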