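comparison	overlap
Transgenic Day 0 vs. Day 28	1
Transgenic Day 0 vs. Day 41	0
Transgenic Day 28 vs. Day 41	0
Non-transgenic Day 0 vs. Day 28	7
Non-transgenic Day 0 vs. Day 41	0
Non-transgenic Day 28 vs. Day 41	1
Transgenic vs. non-transgenic Day 0	0
Transgenic vs. non-transgenic Day 28	8
Transgenic vs. non-transgenic Day 41	0
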