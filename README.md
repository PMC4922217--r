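# phifair

**phifair** turns a pathogen–host interaction database dump — the kind of
bespoke XML that plant-pathology resources distribute for download — into a
FAIR (Findable, Accessible, Interoperable, Reusable) Linked Data resource,
end to end and fully offline:

1. **Parse & select** — read the XML dump (20 curated fields per
   interaction record), restrict it to allowlisted plant hosts.
2. **Harmonize** — map messy free-text fields (`"Reduced virulence,"`,
   `"reduced virulence"` …) to controlled-vocabulary URIs via curated
   identity-mapping tables; resolve common species names to NCBI taxa;
   build typed Identifiers.org cross-references; link diseases to DBpedia.
3. **Model** — emit an SIO-style RDF graph: each record becomes an
   *Interaction* with a *Pathogen* and *Host* participant, two
   *Interaction Contexts* (the implicit wild-type "base state" and the
   recorded mutant state), and an *Allele → Gene → Organism* chain that
   makes genes the convergence point between records. All literal data
   sits behind a single `has value` predicate; every minted node carries
   an opaque URI, one `@en` label and at least one `rdf:type`.
4. **Publish** — a two-layer FAIR Accessor (repository metadata with
   DCAT/SKOS facets, per-record meta-records with dual RDF/HTML
   distributions) plus a resolver that dereferences every minted URI for
   humans (generic HTML) and machines (RDF) from one code path.

Because no RDF stack exists in the target environment, the package carries
its own minimal machinery: a `triple_set` statement container,
deterministic Turtle / RDF-XML / N-Quads serializers with exact
round-trip parsers, and a restricted SPARQL engine sufficient for the
packaged exploration queries (basic graph patterns, `FILTER` with
`!=` / `CONTAINS` / `str()`, `GRAPH`, `SELECT DISTINCT` with `str()-as`
projections). Anything outside that subset raises an error rather than
returning wrong answers.

## The model in brief

```
Interaction ──has_participant──▶ Host ──is_member_of──▶ Organism (taxon URI)
            ──has_participant──▶ Pathogen ──is_member_of──▶ Organism
            ──is_manifested_as─▶ InteractionContext (base state)
            │                      ├─depends_on─▶ HostContext ──has_quality─▶ DiseaseName
            │                      ├─depends_on─▶ PathogenContext (wild-type genotype)
            │                      └─has_quality─▶ Description ─has_value─▶ "BASE STATE"
            └─is_manifested_as─▶ InteractionContext (mutant)
                                   ├─has_quality─▶ Description(phenotype class) ─has_value─▶ label
                                   ├─is_output_of─▶ Investigation(evidence class)
                                   │                  └─schema:citation─▶ Citation ─has_unique_identifier─▶ PubMed URI
                                   └─depends_on─▶ PathogenContext ──has_quality──▶ Allele
                                                     Allele ─variant_of─▶ Gene ─is_proper_part_of─▶ Organism
                                                     Gene ─has_unique_identifier─▶ gene name / locus / xref / GO
```

Organism nodes *are* their Identifiers.org taxonomy URIs
(`http://identifiers.org/taxonomy/4530`), labeled `"Binomial (Common
name)"@en`; cross-reference nodes are Identifiers.org URIs typed with
EDAM identifier-kind concepts (e.g. `http://identifiers.org/uniprot/P22287
a edam:data_3021`).

Minted URIs follow the opaque scheme
`http://<authority>/<project>/Resource/<type>/<PREFIX_NNNNN>`, e.g.
`.../Resource/interaction/INT_00004`, `.../Resource/hostcontext/HOSTCON_000123`.

## The XML dialect

The source dump has no formal schema, so the package fixes one: a
`<Records>` root with one `<Record>` element per interaction, carrying
these tags (unknown sibling tags tolerated; `GO_annotation` and
`Literature_ID` may repeat):

```
PHI-base_accession  DB_Type  Accession  Associated_strain  Gene_name
Locus_ID  Pathogen_NCBI_Taxonomy_ID  Pathogen_species  Strain
Disease_name  Host_NCBI_Taxonomy_ID  Experimental_host  Function
Phenotype_of_mutant  Experimental_evidence  In_vitro_growth
AA_sequence  NT_sequence  GO_annotation  Literature_ID
```

Mapping tables are UTF-8 TSV with a header row; column layouts per
domain are documented in `?load_mapping_table`. Default tables covering
the fixture pools ship under `inst/extdata/`.

## Worked example

```r
library(phifair)

rec  <- reference_record()              # fixed example record PHI:11
tabs <- default_mapping_tables()
cfg  <- accessor_config()
tr   <- transform_records(list(rec), tabs, named_graph = cfg$base_url)

nrow(tr$graph)
#> [1] 112
tr$interactions
#>   accession     token                                                      uri
#> 1    PHI:11 INT_00001 http://linkeddata.systems/SemanticPHIBase/Resource/interaction/INT_00001

sparql_select(packaged_query(2), tr$graph)   # hosts of Magnaporthe interactions
#>           hostspecies
#> 1 Oryza sativa (Rice)

sparql_select(packaged_query(7), tr$graph)$provenance[1]  # named-graph provenance
#> [1] "http://linkeddata.systems/SemanticPHIBase/Metadata"

nrow(validate_graph(tr$graph))          # empty report = model-conformant
#> [1] 0

svc <- phi_service(tr, cfg)
resolve_request(svc, tr$interactions$uri, "text/html")$status        # humans
#> [1] 200
resolve_request(svc, tr$interactions$uri, "application/rdf+xml")$status  # machines
#> [1] 200
```

The 112 statements are the full semantic rendering of one record:
interaction, participants, deduplicated taxon nodes, both contexts, the
phenotype/evidence classes, the UniProt/locus/GO identifiers and the
PubMed citation. The Query 2 row shows the harmonized organism label
(binomial + common name), which is what makes both scientific- and
common-name text filters work. The Query 7 value is the accessor URL
used as the named graph, i.e. every data point carries a resolvable
pointer to its repository-level provenance metadata.

Synthetic data at scale:

```r
fx <- generate_fixture(fixture_spec(50, seed = 1,
        messiness = list(case = .5, punct = .5, common = .5, missing = .5)))
tr <- transform_records(fx$records, fx$tables,
                        named_graph = accessor_config()$base_url)
```

A command-line wrapper covers the same pipeline:
`Rscript -e 'phifair::phifair_cli()' transform --in records.xml
--tables tables/ --allowlist plants.tsv --out out/`.

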