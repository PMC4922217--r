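# Query 3: genes affecting Magnaporthe infection, phenotypic outcomes
# of allele variants, organized by host species
PREFIX PHIO: <http://linkeddata.systems/SemanticPHIBase/Resource/>
PREFIX EDAM: <http://edamontology.org/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>

SELECT DISTINCT ?int str(?species1) as ?Pathogen str(?genename) as ?Locus
str(?species2) as ?Host str(?pheno) as ?Phenotype
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
   ?gene PHIO:is_proper_part_of ?organism1.
   ?gene PHIO:has_unique_identifier ?geneid.
   ?geneid a EDAM:data_2299.
   ?geneid PHIO:has_value ?genename.
   ?int PHIO:is_manifested_as ?intcont.
   ?intcont PHIO:has_quality ?desc.
   ?desc PHIO:has_value ?pheno.
   FILTER(!str(?pheno) = "BASE STATE")
}
ORDER BY ?organism2
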