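comparison	down	up
Transgenic Day 0 vs. Day 28	253	652
Transgenic Day 0 vs. Day 41	11	10
Transgenic Day 28 vs. Day 41	700	162
Non-transgenic Day 0 vs. Day 28	829	1508
Non-transgenic Day 0 vs. Day 41	639	156
Non-transgenic Day 28 vs. Day 41	1524	740
Transgenic vs. non-transgenic Day 0	154	108
Transgenic vs. non-transgenic Day 28	367	317
Transgenic vs. non-transgenic Day 41	627	253
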