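raw	canonical_label	uri
Gene disruption	Gene disruption	http://linkeddata.systems/ontologies/SemanticPHIBase#EVID_gene_disruption
Gene deletion	Gene deletion	http://linkeddata.systems/ontologies/SemanticPHIBase#EVID_gene_deletion
Gene complementation	Gene complementation	http://linkeddata.systems/ontologies/SemanticPHIBase#EVID_gene_complementation
RNA interference	RNA interference	http://linkeddata.systems/ontologies/SemanticPHIBase#EVID_rna_interference
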