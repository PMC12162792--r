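comparison	hypo	hyper
Transgenic Day 0 vs. Day 28	5	6
Transgenic Day 0 vs. Day 41	5	9
Transgenic Day 28 vs. Day 41	8	13
Non-transgenic Day 0 vs. Day 28	7	18
Non-transgenic Day 0 vs. Day 41	15	17
Non-transgenic Day 28 vs. Day 41	12	16
Transgenic vs. non-transgenic Day 0	15	15
Transgenic vs. non-transgenic Day 28	35	21
Transgenic vs. non-transgenic Day 41	26	19
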