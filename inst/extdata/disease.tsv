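raw	uri
Rice blast	http://dbpedia.org/resource/Rice_blast
Head blight	http://dbpedia.org/resource/Fusarium_ear_blight
Late blight	http://dbpedia.org/resource/Phytophthora_infestans
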