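taxon_id	name_pattern
4530	Oryza sativa
4565	Triticum aestivum
4577	Zea mays
4081	Solanum lycopersicum
4513	Hordeum vulgare
3702	Arabidopsis thaliana
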