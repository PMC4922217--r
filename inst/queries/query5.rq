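# Query 5: GO annotations of Magnaporthe genes whose mutant alleles
# cause hypervirulence on rice
# network-required: federates to identifiers.org and sparql.uniprot.org;
# not executable by the local engine
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX EDAM: <http://edamontology.org/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX up: <http://purl.uniprot.org/core/>
PREFIX owl: <http://www.w3.org/2002/07/owl#>

SELECT DISTINCT (str(?species1) as ?Pathogen) (str(?genename) as ?Locus) ?protid
?uniprot (str(?species2) as ?Host) (str(?pheno) as ?Phenotype) ?goterm
WHERE {
    {
   SELECT DISTINCT ?protid ?species1 ?genename ?species2 ?pheno
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
        FILTER(CONTAINS(?species2, "Rice")).
        ?gene PHIO:is_proper_part_of ?organism1.
        ?gene PHIO:has_unique_identifier ?geneid.
        ?geneid a EDAM:data_2299. # Gene Name
        ?geneid PHIO:has_value ?genename.
        ?gene PHIO:has_unique_identifier ?protid.
        ?protid a EDAM:data_2291. # UniProt Identifier
        ?int PHIO:is_manifested_as ?intcont.
        ?intcont PHIO:has_quality ?desc.
        ?desc PHIO:has_value ?pheno.
        FILTER(CONTAINS(str(?pheno), "Increased virulence"))
      }
   }
   SERVICE <http://identifiers.org/services/sparql> {
     ?protid owl:sameAs ?uniprot.
     FILTER(CONTAINS(str(?uniprot), "purl.uniprot"))
   }
   SERVICE <http://sparql.uniprot.org/sparql> {
        ?uniprot up:classifiedWith ?annot.
        ?annot rdfs:label ?goterm.
        ?annot a owl:Class.
   }
}
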