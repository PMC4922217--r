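# Query 2: what organisms are hosts for Magnaporthe species?
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>

SELECT DISTINCT (str(?species2) as ?hostspecies)
WHERE {
   ?int a PHIO:PHIBO_00022.
   ?int PHIO:has_participant ?part1.
   ?int PHIO:has_participant ?part2.
   FILTER(?part1 != ?part2).
   ?part1 PHIO:is_member_of ?organism1.
   ?organism1 rdfs:label ?species1.
   FILTER (CONTAINS (?species1, "Magnaporthe")).
   ?part2 PHIO:is_member_of ?organism2.
   ?organism2 rdfs:label ?species2.
}
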