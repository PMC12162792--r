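comparison	hypo	hyper
Transgenic Day 0 vs. Day 28	1860	1550
Transgenic Day 0 vs. Day 41	819	1096
Transgenic Day 28 vs. Day 41	3791	4987
Non-transgenic Day 0 vs. Day 28	5718	8414
Non-transgenic Day 0 vs. Day 41	6442	6569
Non-transgenic Day 28 vs. Day 41	1807	1157
Transgenic vs. non-transgenic Day 0	8418	9382
Transgenic vs. non-transgenic Day 28	20421	14847
Transgenic vs. non-transgenic Day 41	9657	8098
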