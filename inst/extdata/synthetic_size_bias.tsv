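size	efficiency
150	1.00
200	0.95
250	0.85
300	0.70
350	0.55
400	0.42
450	0.32
500	0.25
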