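window_size	dmr_count	overlap_count
100	3106	111
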