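# Namespace constants used throughout the model, the accessor and the
# packaged queries.  PHIO is the resolver namespace in which the model's
# classes and predicates are minted (the packaged queries resolve the
# PHIO: prefix there); ONT is the local ontology namespace used for
# harmonized controlled-vocabulary classes.
NS <- list(
  rdf_type    = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
  rdfs_label  = "http://www.w3.org/2000/01/rdf-schema#label",
  rdfs_seealso = "http://www.w3.org/2000/01/rdf-schema#seeAlso",
  rdfs_comment = "http://www.w3.org/2000/01/rdf-schema#comment",
  rdfs_subprop = "http://www.w3.org/2000/01/rdf-schema#subPropertyOf",
  owl_class   = "http://www.w3.org/2002/07/owl#Class",
  owl_objprop = "http://www.w3.org/2002/07/owl#ObjectProperty",
  skos        = "http://www.w3.org/2004/02/skos/core#",
  dc11        = "http://purl.org/dc/elements/1.1/",
  dcat        = "http://www.w3.org/ns/dcat#",
  dctypes     = "http://purl.org/dc/dcmitype/",
  void        = "http://rdfs.org/ns/void#",
  pav         = "http://purl.org/pav/",
  prov        = "http://www.w3.org/ns/prov#",
  daml        = "http://www.ksl.stanford.edu/projects/DAML/ksl-daml-desc.daml#",
  foaf        = "http://xmlns.com/foaf/0.1/",
  ldp         = "http://www.w3.org/ns/ldp#",
  schema      = "http://schema.org/",
  edam        = "http://edamontology.org/",
  sio         = "http://semanticscience.org/resource/",
  efo         = "http://www.ebi.ac.uk/efo/",
  obo         = "http://purl.obolibrary.org/obo/",
  idorg       = "http://identifiers.org/",
  idorg_taxonomy = "http://identifiers.org/taxonomy/",
  idorg_pubmed   = "http://identifiers.org/pubmed/",
  idorg_go       = "http://identifiers.org/go/"
)

#' The model vocabulary: class and predicate URIs of the semantic model
#'
#' Collects every URI the record-graph builder emits: locally minted model
#' classes and predicates (in the resolver namespace, so the packaged
#' SPARQL queries' `PHIO:` prefix resolves them), harmonized-vocabulary
#' namespaces, and the external ontology terms used for multi-typing
#' (EFO/SIO role terms, OBI/SIO organism, EFO wild-type genotype, EDAM
#' identifier kinds, schema.org CreativeWork).
#'
#' External term URIs that the model requires but whose exact identifiers
#' are conventions of this package (rather than community-fixed) are
#' ordinary list entries and may be overridden.
#'
#' @param scheme a [uri_scheme()]; determines the namespaces in which
#'   local classes/predicates are minted.
#' @return A named list of absolute URIs with class `phi_vocabulary`.
#' @examples
#' v <- model_vocabulary()
#' v$cls_interaction
#' @export
model_vocabulary <- function(scheme = uri_scheme()) {
  res <- paste0(scheme$authority, "/", scheme$project, "/", scheme$resolver, "/")
  ont <- scheme$ontology_ns
  structure(list(
    resource_ns = res,
    ontology_ns = ont,
    # classes -- the Interaction class URI is the one the packaged
    # queries type-match on (PHIO:PHIBO_00022)
    cls_interaction         = paste0(res, "PHIBO_00022"),
    cls_interaction_context = paste0(ont, "InteractionContext"),
    cls_host_context        = paste0(ont, "HostContext"),
    cls_pathogen_context    = paste0(ont, "PathogenContext"),
    cls_host                = paste0(ont, "Host"),
    cls_pathogen            = paste0(ont, "Pathogen"),
    cls_organism            = paste0(ont, "Organism"),
    cls_gene                = paste0(ont, "Gene"),
    cls_allele              = paste0(ont, "Allele"),
    cls_description         = paste0(ont, "Description"),
    cls_investigation       = paste0(ont, "Investigation"),
    cls_citation            = paste0(ont, "Citation"),
    cls_disease_name        = paste0(ont, "DiseaseName"),
    cls_strain              = paste0(ont, "StrainDescription"),
    cls_growth              = paste0(ont, "InVitroGrowthDescription"),
    cls_function            = paste0(ont, "FunctionDescription"),
    cls_sequence            = paste0(ont, "SequenceQuality"),
    # predicates (minted in the resolver namespace; mirrored to their
    # RO/SIO/schema.org sources via subPropertyOf in the shipped ontology)
    has_participant       = paste0(res, "has_participant"),
    participates_in       = paste0(res, "participates_in"),
    depends_on            = paste0(res, "depends_on"),
    is_manifested_as      = paste0(res, "is_manifested_as"),
    is_member_of          = paste0(res, "is_member_of"),
    is_proper_part_of     = paste0(res, "is_proper_part_of"),
    variant_of            = paste0(res, "variant_of"),
    has_quality           = paste0(res, "has_quality"),
    has_unique_identifier = paste0(res, "has_unique_identifier"),
    has_value             = paste0(res, "has_value"),
    is_output_of          = paste0(res, "is_output_of"),
    citation              = paste0(NS$schema, "citation"),
    # external multi-typing terms.  Host/organism identifiers are
    # community-fixed; the remaining role terms are package defaults.
    ext_host      = c(paste0(NS$efo, "EFO_0000532"), paste0(NS$sio, "SIO_010415")),
    ext_pathogen  = c(paste0(NS$efo, "EFO_0000643"), paste0(NS$sio, "SIO_010423")),
    ext_organism  = c(paste0(NS$obo, "OBI_0100026"), paste0(NS$sio, "SIO_010000")),
    ext_wild_type_genotype = paste0(NS$efo, "EFO_0005168"),
    ext_gene               = paste0(NS$obo, "SO_0000704"),
    ext_creative_work      = paste0(NS$schema, "CreativeWork"),
    # EDAM identifier-kind concepts with printed community identifiers;
    # the remaining kinds arrive through the dbtype/term mapping tables.
    edam_gene_name    = paste0(NS$edam, "data_2299"),
    edam_protein_acc  = paste0(NS$edam, "data_2907"),
    edam_uniprot_acc  = paste0(NS$edam, "data_3021"),
    edam_locus_id     = paste0(NS$edam, "data_1893"),
    edam_go_id        = paste0(NS$edam, "data_1176"),
    edam_taxonomy_id  = paste0(NS$edam, "data_1179"),
    edam_pubmed_id    = paste0(NS$edam, "data_1187"),
    edam_protein_seq  = paste0(NS$edam, "data_2976"),
    edam_nucleotide_seq = paste0(NS$edam, "data_2977")
  ), class = "phi_vocabulary")
}

#' Emit the shipped ontology graph for the local vocabulary
#'
#' Declares every locally minted class and predicate with a label, and
#' mirrors each model predicate to its RO/SIO/schema.org source term via
#' `rdfs:subPropertyOf`, so consumers reasoning over the community
#' ontologies can interpret the local predicates.
#'
#' @param vocab a [model_vocabulary()].
#' @return A `phi_triples` graph describing the vocabulary.
#' @export
ontology_graph <- function(vocab = model_vocabulary()) {
  ts <- triple_set()
  classes <- list(
    c(vocab$cls_interaction, "Interaction"),
    c(vocab$cls_interaction_context, "Interaction Context"),
    c(vocab$cls_host_context, "Host Context"),
    c(vocab$cls_pathogen_context, "Pathogen Context"),
    c(vocab$cls_host, "Host"), c(vocab$cls_pathogen, "Pathogen"),
    c(vocab$cls_organism, "Organism"), c(vocab$cls_gene, "Gene"),
    c(vocab$cls_allele, "Allele"), c(vocab$cls_description, "Description"),
    c(vocab$cls_investigation, "Investigation"),
    c(vocab$cls_citation, "Citation"),
    c(vocab$cls_disease_name, "Disease Name"),
    c(vocab$cls_strain, "Strain Description"),
    c(vocab$cls_growth, "In Vitro Growth Description"),
    c(vocab$cls_function, "Function Description"),
    c(vocab$cls_sequence, "Sequence Quality")
  )
  for (cl in classes) {
    ts <- ts_add(ts, cl[1], NS$rdf_type, NS$owl_class)
    ts <- ts_add(ts, cl[1], NS$rdfs_label, lit(cl[2], "en"))
  }
  ro <- paste0(NS$obo, "ro.owl#")
  mirrors <- list(
    c(vocab$has_participant, paste0(ro, "has_participant")),
    c(vocab$participates_in, paste0(ro, "participates_in")),
    c(vocab$depends_on, paste0(ro, "depends_on")),
    c(vocab$is_manifested_as, paste0(NS$sio, "SIO_000883")),
    c(vocab$is_member_of, paste0(NS$sio, "SIO_000095")),
    c(vocab$is_proper_part_of, paste0(NS$sio, "SIO_000093")),
    c(vocab$variant_of, paste0(NS$sio, "SIO_000272")),
    c(vocab$has_quality, paste0(NS$sio, "SIO_000217")),
    c(vocab$has_unique_identifier, paste0(NS$sio, "SIO_000674")),
    c(vocab$has_value, paste0(NS$sio, "SIO_000300")),
    c(vocab$is_output_of, paste0(NS$sio, "SIO_000232"))
  )
  for (m in mirrors) {
    ts <- ts_add(ts, m[1], NS$rdf_type, NS$owl_objprop)
    ts <- ts_add(ts, m[1], NS$rdfs_label,
                 lit(gsub("_", " ", basename(m[1])), "en"))
    ts <- ts_add(ts, m[1], NS$rdfs_subprop, m[2])
  }
  ts
}
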