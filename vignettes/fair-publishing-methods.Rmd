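---
title: "Methods: FAIR publication of pathogen-host interaction records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FAIR publication of pathogen-host interaction records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phifair)
```

## The problem

Curated pathogen–host interaction databases hold phenotype observations
— "knocking out gene X in pathogen Y reduces virulence on host Z" —
that plant pathologists need to combine with sequence, taxonomy and
literature resources. Distributed as schema-less XML behind a manual
download, those observations are invisible to machines: fields are free
text with inconsistent capitalization and punctuation, species appear
under common names, and cross-references are bare accession strings
whose source database a human infers from context.

`phifair` implements a complete FAIR transformation of such a dump:
identifier minting, vocabulary harmonization, an observational RDF
model, repository/record metadata, and dual human/machine
dereferencing. Everything runs offline against synthetic fixtures, so
the pipeline is testable without the licensed source data.

## The semantic model and its assumptions

The model follows the observational-data conventions of the
Semanticscience Integrated Ontology (SIO). Its load-bearing choices:

* **Literals only behind `has value`.** No datum is attached by an
  ad-hoc predicate; every value (phenotype text, sequence, strain name,
  disease name) hangs off an entity node through the single `has value`
  predicate. Generic consumers therefore always know where the data is,
  and every datum has its own annotatable, citable node.
* **Explicit base state.** Every record implies a comparison against
  the wild-type pathogen on a susceptible host. The model materializes
  it: each *Interaction* is manifested as at least two *Interaction
  Contexts* — a base state whose Description literally reads
  `"BASE STATE"` and whose Pathogen Context is typed as a wild-type
  genotype, and a mutant state carrying the harmonized phenotype, the
  experimental evidence (*Investigation*) and the citation chain. The
  context container also leaves a natural slot for an environmental
  context, which the source data does not populate.
* **Genes converge, alleles do not.** Each record mints its own
  *Allele* (absent evidence that two studies used the same allele), but
  alleles of the same gene in the same pathogen share one *Gene* node
  (identity key: pathogen taxon + gene name, falling back to locus ID,
  then accession). The Gene node is where cross-record and cross-source
  queries meet: it carries the typed identifier nodes (gene name, locus
  ID, sequence-database cross-reference, GO annotations) and the
  sequence qualities.
* **Organisms are Identifiers.org taxon URIs.** Rather than minting a
  local organism node that *points at* the taxon, the organism node *is*
  `http://identifiers.org/taxonomy/<id>`. This makes deduplication
  automatic and lets federated queries hand the node straight to the
  Identifiers.org same-as service. Organism labels are
  `"Binomial (Common name)"@en` so that both scientific-name and
  common-name text filters match.
* **Multi-typing.** Organism nodes carry four external types (EFO and
  SIO role terms plus OBI and SIO organism terms); identifier nodes are
  typed with EDAM identifier-kind concepts. Redundant typing broadens
  the set of agents that can interpret the data; it costs nothing.

Two placements are package conventions because the source model leaves
them open: free-text *Function* attaches as a quality of the Gene, and
*In vitro growth* as a harmonized quality of the mutant Pathogen
Context. The validation report lists such nodes in its `notes`
attribute. Similarly `Strain` attaches to the mutant Pathogen Context
and `Associated_strain` to the wild-type one. The disease node attaches
to the base-state *Host* Context (the diseased wild-type host): keeping
disease out of the Interaction Context's qualities is what lets the
packaged phenotype query distinguish phenotype descriptions by a single
`"BASE STATE"` filter.

## Identifiers

Minted URIs are opaque:
`<authority>/<project>/Resource/<type>/<PREFIX>_<zero-padded serial>`,
with no key/value parameters (resolver software changes; identifiers
must not). Pad widths follow the published exemplars (5 digits for
interaction/host/pathogen/gene tokens, 6 for contexts and data nodes)
and overflow is an error, never silent widening. Serials are assigned
in record-accession sort order, so a re-run over the same input mints
identical URIs — determinism the test suite asserts byte-for-byte.

## Harmonization

The cleansing step is identity mapping: curated TSV tables assign every
semantically identical raw string one controlled-vocabulary URI. Before
lookup, keys are normalized by case-folding, whitespace collapsing and
trailing-punctuation stripping — the minimal rule covering the defect
classes actually observed (capitalization and punctuation). Semantic
merging beyond that rule (lexically distant synonyms) is strictly
table-driven; the code never guesses.

Policies on a lookup miss: `strict` (the default) raises a classed
error; `mint` coins a deterministic URI in the local ontology namespace
(fragment = slugified normalized string) and logs the miss to the
unmapped-terms report. Unknown `DB_Type` values are non-fatal either
way: the record survives, only its cross-reference is dropped and
logged, because a dropped cross-reference is recoverable and a dropped
record is not. Disease lookup never fails: unmapped names get a
deterministic local URI.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `uri_scheme()` authority/project | `http://linkeddata.systems/SemanticPHIBase` | published namespace of the original deployment; configurable because namespaces are institutional accidents |
| pad widths | 5 / 6 digits | printed exemplars (`INT_00004`, `HOSTCON_000123`) |
| harmonization policy | `strict` | a silent vocabulary drift is worse than a loud failure |
| `accessor_config()` facets | the original deployment's values | a default-configured accessor is complete; every value is configuration, nothing personal is hard-coded in the model code |
| fixture `messiness` | 0.3 each (0.5 in acceptance runs) | roughly half of descriptive strings perturbed exercises the normalization rule hard while staying within its stated reach |
| fixture size | 50 records | large enough for gene-sharing and query variety, small enough for seconds-scale tests |

## What the synthetic generator emulates — and what it does not

`generate_fixture()` emulates the documented defects of the real dump:
case and punctuation perturbation of descriptive terms (always within
reach of the normalization rule), common-name species entries, sparse
optional fields, repeated multi-valued tags, and cross-record gene
sharing. Taxa and a handful of term strings are real (rice, wheat,
rice-blast fungus, "Reduced virulence"…) so the packaged queries read
naturally; everything else — accessions, sequences, PubMed IDs — is
synthetic and labeled as such.

It does **not** emulate: the real corpus's size (3000+ records) or field
distributions, lexically-distant synonym pairs (those are a curation
problem, not a code problem), genuinely malformed records, or nested
record structures. A green suite therefore establishes that the
machinery is correct on well-formed-but-messy input with complete
mapping tables; it does not establish recall against the real database.

## Publication layers

The repository "homepage for machines" serves, at one URL: type
declarations (PROV Collection + DCTypes Dataset), citation and license
facets, both `dc:language` and `dcat:language` values exactly as
configured (the original printed two different language URIs; the
package reproduces rather than reconciles them), a SKOS concept scheme
as the machine keyword list, and the list of per-record meta-record
URIs (LDP-style, optionally paginated, off by default). Each
meta-record exposes exactly two typed `dcat:distribution`s: the minted
interaction URI (`application/rdf+xml`) and the original web record
(`text/html`).

The data graph is named by the accessor URL: N-Quads output stamps
every statement with it, and the packaged provenance query
(`GRAPH ?provenance { ... }`) returns it, so any data point resolves to
citable repository metadata. This symmetry — metadata lists the data,
data names the metadata — is asserted by the acceptance tests.

The resolver is a single code path: a URI's subject-position subgraph
(the DESCRIBE scope; inbound statements behind a flag) is extracted
once and rendered either as RDF or as generic property-list HTML.
Media selection is HTTP content negotiation with a browser-first
default; a compatibility flag reproduces the historical
XML-stylesheet-in-RDF/XML trick byte-for-byte in spirit (the
processing instruction referencing `styles/phi.xsl`). The service is a
pure function (`resolve_request(service, path, accept)`) rather than a
bound socket: the environment provides no HTTP server package, and the
contract under test is resolution, not networking.

## Numerical and formatting choices

* Serialization is deterministic: statements are radix-sorted on
  (subject, predicate, object kind, object) before writing, so equal
  graphs produce byte-identical documents and diffs are meaningful.
* Turtle output is restricted to the absolute-IRI line-oriented subset
  (every line is also valid N-Triples); graphs here contain no blank
  nodes, so round-trip isomorphism is exact set equality and is tested
  for all three formats.
* The SPARQL engine implements exactly the subset the packaged local
  queries use and raises a classed error on anything else — a wrong
  answer would be worse than a refusal. The federated queries (images,
  GO annotations, MeSH terms) ship as text marked `network-required`
  and are never executed by the engine.
* Record processing order, and therefore URI assignment, is the radix
  (C-locale) sort of accessions — locale-independent by construction.
* Sequences are stored case-folded and whitespace-stripped; alphabet
  checks accept the IUPAC ambiguity codes.

## Known limitations

* Graph storage is an in-memory data frame; fine for 10^5–10^6
  statements, not a triplestore replacement.
* The harmonizer cannot merge lexically distant synonyms without a
  table row; the unmapped-terms report exists precisely to drive that
  curation loop.
* The SPARQL subset excludes OPTIONAL, sub-SELECT scoping, property
  paths and SERVICE; queries needing them must run on a real endpoint
  loaded from the N-Quads export.
* Whether the real dump nests interactions under genes is unknown; the
  canonical dialect treats each interaction as one flat record, and one
  XML record maps to exactly one Interaction node.
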