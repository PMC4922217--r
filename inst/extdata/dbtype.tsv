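raw	prefix	edam_uri
UNIPROT	http://identifiers.org/uniprot/	http://edamontology.org/data_3021
ENTREZ PROTEIN	http://identifiers.org/ena.embl/	http://edamontology.org/data_2907
EMBL	http://identifiers.org/ena.embl/	http://edamontology.org/data_2907
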