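group	n_obis	n_bold	n_sep
Chile	2563	1019	119
Peru	1184	619	73
Ecuador	1863	993	80
Colombia	1695	950	2
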