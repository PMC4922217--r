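# Query 1: overview of the interactions in the store
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>

SELECT DISTINCT ?s ?l
WHERE {
   ?s a PHIO:PHIBO_00022.
   ?s rdfs:label ?l
}
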