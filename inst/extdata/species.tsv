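raw	scientific_name	taxon_id	rank	common_name
Magnaporthe oryzae	Magnaporthe oryzae	318829	species	Rice blast fungus
Fusarium graminearum	Fusarium graminearum	5518	species	
Botrytis cinerea	Botrytis cinerea	40559	species	Grey mould fungus
Ustilago maydis	Ustilago maydis	5270	species	Corn smut fungus
Phytophthora infestans	Phytophthora infestans	4787	species	
Fusarium	Fusarium	5506	genus	
Oryza sativa	Oryza sativa	4530	species	Rice
Triticum aestivum	Triticum aestivum	4565	species	Wheat
Zea mays	Zea mays	4577	species	Maize
Solanum lycopersicum	Solanum lycopersicum	4081	species	Tomato
Hordeum vulgare	Hordeum vulgare	4513	species	Barley
Arabidopsis thaliana	Arabidopsis thaliana	3702	species	Thale cress
Mus musculus	Mus musculus	10090	species	Mouse
Homo sapiens	Homo sapiens	9606	species	Human
Rice blast fungus	Magnaporthe oryzae	318829	species	Rice blast fungus
Grey mould fungus	Botrytis cinerea	40559	species	Grey mould fungus
Corn smut fungus	Ustilago maydis	5270	species	Corn smut fungus
Rice	Oryza sativa	4530	species	Rice
Wheat	Triticum aestivum	4565	species	Wheat
Maize	Zea mays	4577	species	Maize
Tomato	Solanum lycopersicum	4081	species	Tomato
Barley	Hordeum vulgare	4513	species	Barley
Thale cress	Arabidopsis thaliana	3702	species	Thale cress
Mouse	Mus musculus	10090	species	Mouse
Human	Homo sapiens	9606	species	Human
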