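raw	canonical_label	uri
Normal growth	Normal growth	http://linkeddata.systems/ontologies/SemanticPHIBase#IN_V_normal_growth
Reduced growth	Reduced growth	http://linkeddata.systems/ontologies/SemanticPHIBase#IN_V_reduced_growth
No change	No change	http://linkeddata.systems/ontologies/SemanticPHIBase#IN_V_no_change
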