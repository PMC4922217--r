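raw	canonical_label	uri
Reduced virulence	Reduced virulence	http://linkeddata.systems/ontologies/SemanticPHIBase#PHEN_reduced_virulence
Increased virulence	Increased virulence	http://linkeddata.systems/ontologies/SemanticPHIBase#PHEN_increased_virulence
Loss of pathogenicity	Loss of pathogenicity	http://linkeddata.systems/ontologies/SemanticPHIBase#PHEN_loss_of_pathogenicity
Unaffected pathogenicity	Unaffected pathogenicity	http://linkeddata.systems/ontologies/SemanticPHIBase#PHEN_unaffected_pathogenicity
Lethal	Lethal	http://linkeddata.systems/ontologies/SemanticPHIBase#PHEN_lethal
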