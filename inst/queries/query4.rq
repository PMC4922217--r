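# Query 4: images of Magnaporthe host species from UniProt
# network-required: federates to identifiers.org and sparql.uniprot.org;
# not executable by the local engine
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX foaf: <http://xmlns.com/foaf/0.1/>
PREFIX owl: <http://www.w3.org/2002/07/owl#>

SELECT ?hostspecies ?picture
WHERE {
   {
   SELECT DISTINCT (str(?species2) as ?hostspecies) ?organism2
     WHERE {
        ?int a PHIO:PHIBO_00022.
        ?int PHIO:has_participant ?part1.
        ?int PHIO:has_participant ?part2.
        FILTER(?part1 != ?part2).
        ?part1 PHIO:is_member_of ?organism1.
        ?organism1 rdfs:label ?species1.
        FILTER(CONTAINS(?species1, "Magnaporthe")).
        ?part2 PHIO:is_member_of ?organism2.
        ?organism2 rdfs:label ?species2.
        FILTER(CONTAINS(str(?organism2), "identifiers.org"))
      }
   }
   SERVICE <http://identifiers.org/services/sparql> {
        ?organism2 owl:sameAs ?crossref.
        FILTER(CONTAINS(str(?crossref), "purl.uniprot"))
   }
   SERVICE <http://sparql.uniprot.org/sparql> {
        OPTIONAL{?crossref foaf:depiction ?picture}
   }
}
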