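distant_recurrence	GLUT1_low	GLUT1_high
No	27	4
Yes	10	7
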