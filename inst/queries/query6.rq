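# Query 6: MeSH terms of publications describing Magnaporthe-wheat
# interactions
# network-required: federates to identifiers.org and linkedlifedata.com;
# not executable by the local engine
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX PUBMED: <http://linkedlifedata.com/resource/pubmed/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX schema: <http://schema.org/>
PREFIX owl: <http://www.w3.org/2002/07/owl#>

select distinct ?intlabel ?pubmed ?meshterm
where {
   {select distinct ?pubmed ?intlabel
    where {
        {select distinct ?pmid ?intlabel
         where {
           ?int a PHIO:PHIBO_00022.
           ?int rdfs:label ?intlabel.
           ?int PHIO:has_participant ?part1.
           ?int PHIO:has_participant ?part2.
           FILTER(?part1 != ?part2).
           ?int PHIO:is_manifested_as ?intcont.
           ?intcont PHIO:is_output_of ?investigation.
           ?investigation schema:citation ?cite.
           ?cite PHIO:has_unique_identifier ?pmid.
           ?part1 PHIO:is_member_of ?organism1.
           ?organism1 rdfs:label ?species1.
           ?part2 PHIO:is_member_of ?organism2.
           ?organism2 rdfs:label ?species2.
           FILTER(CONTAINS(?species1, "Magnaporthe")).
           FILTER(CONTAINS(?species2, "Wheat")).
         }}
         SERVICE <http://identifiers.org/services/sparql> {
           ?pmid owl:sameAs ?pubmed.
           FILTER(CONTAINS(str(?pubmed), "linkedlifedata"))
         }
   }}
   SERVICE <http://linkedlifedata.com/sparql/> {
  OPTIONAL {?pubmed PUBMED:meshHeading ?mh.
  ?mh PUBMED:mesh ?mesh.
  ?mesh rdfs:label ?meshterm}
   }
}
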