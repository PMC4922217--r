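# Two-layer FAIR Accessor ----------------------------------------------------
#
# Layer 1: repository-level metadata -- a "homepage for machines" at the
# accessor URL carrying title/type/authorship/license/keyword facets, a
# SKOS concept scheme as the machine-readable keyword list, and the list
# of record-level meta-record URIs (Linked Data Platform style).
# Layer 2: one meta-record per interaction, exposing exactly two typed
# distributions of the record: its RDF form (the minted interaction URI)
# and its original HTML page.

is_uri_value <- function(x) grepl("^[a-z][a-z0-9+.-]*://", x)

add_values <- function(ts, subject, predicate, values, lang = NA_character_) {
  for (v in values) {
    ts <- if (is_uri_value(v)) ts_add(ts, subject, predicate, v)
          else ts_add(ts, subject, predicate, lit(v, lang))
  }
  ts
}

#' Repository-level metadata configuration
#'
#' All facet values -- names, ORCID URIs, dates, URLs, keywords, theme
#' concepts -- are configuration; the defaults reproduce the facet set of
#' the original deployment so a default-configured accessor is complete.
#' Values that look like URIs are emitted as resources, everything else
#' as plain literals.
#'
#' @param base_url the accessor URL (also the named-graph / provenance
#'   identifier of the data).
#' @param title repository title.
#' @param technical_leads,principal_investigators character vectors
#'   (human-readable names).
#' @param authored_by ORCID URIs.
#' @param pages,landing_page,creator,contact_point,publishers URLs (or
#'   names, for publishers).
#' @param issued ISO-8601 date string.
#' @param language_dc,language_dcat language URIs (the deployment
#'   printed both a lexvo and an id.loc.gov value; both are emitted as
#'   configured, no reconciliation is attempted).
#' @param license license URI.
#' @param identifier identifier URI (defaults to `base_url`).
#' @param keywords character vector.
#' @param description free-text description.
#' @param theme URI of the SKOS concept-scheme document.
#' @param theme_concepts list of `list(uri=, label=, definition=)`.
#' @param record_url_template `sprintf` template building the original
#'   HTML record URL from an accession.
#' @param record_keywords keywords attached to each meta-record.
#' @param page_size optional integer: when set, the meta-record list is
#'   paginated with next-page links; default off.
#' @return An `phi_accessor_config` object; missing mandatory facets are
#'   a configuration error at construction time.
#' @export
accessor_config <- function(
    base_url = "http://linkeddata.systems/SemanticPHIBase/Metadata",
    title = "Semantic PHI-base",
    technical_leads = c("Dr. Alejandro Rodriguez Gonzalez",
                        "Alejandro Rodriguez Iglesias"),
    principal_investigators = c("Dr. Mark Wilkinson",
                                "Dr. Kim Hammond-Kosack"),
    authored_by = c("http://orcid.org/0000-0002-9699-485X",
                    "http://orcid.org/0000-0002-6019-7306"),
    pages = c("http://linkeddata.systems:8890/sparql",
              "http://www.phi-base.org/"),
    creator = "http://www.phi-base.org/",
    issued = "2015-11-17",
    language_dc = "http://lexvo.org/id/iso639-3/eng",
    language_dcat = "http://id.loc.gov/vocabulary/iso639-1/en",
    license = "http://purl.org/NET/rdflicense/cc-by-nd4.0",
    identifier = base_url,
    keywords = c("pathogenesis", "plant/pathogen interactions",
                 "genetic database", "phytopathology"),
    landing_page = "http://www.phi-base.org/",
    description = paste("FAIR Accessor server for the Semantic PHI-base.",
                        "This server exposes the plant portion of the",
                        "Pathogen Host Interaction database as Linked Data."),
    contact_point = "http://biordf.org/DataFairPort/MiscRDF/Wilkinson.rdf",
    publishers = c("http://wilkinsonlab.info", "Rothamsted Research",
                   "http://www.rothamsted.ac.uk", "http://www.phi-base.org"),
    theme = "http://linkeddata.systems/ConceptSchemes/semanticphi_concept_scheme.rdf",
    theme_concepts = default_theme_concepts(),
    record_url_template = "http://www.phi-base.org/query.php?detail=yes&phi_acc=%s",
    record_keywords = c("PHI Base", "host/pathogen interaction",
                        "pathogenesis"),
    page_size = NULL) {
  cfg <- structure(as.list(environment()), class = "phi_accessor_config")
  mandatory <- c("base_url", "title", "technical_leads",
                 "principal_investigators", "authored_by", "pages",
                 "creator", "issued", "language_dc", "language_dcat",
                 "license", "identifier", "keywords", "landing_page",
                 "description", "contact_point", "publishers", "theme")
  for (f in mandatory)
    if (length(cfg[[f]]) == 0 || !any(nzchar(cfg[[f]])))
      phi_stop("phi_bad_config", sprintf("accessor facet '%s' is unset", f))
  for (f in c("license", "theme"))
    if (!is_uri_value(cfg[[f]]))
      phi_stop("phi_bad_config", sprintf("facet '%s' must be a URI", f))
  for (concept in cfg$theme_concepts)
    if (is.null(concept$label) || !nzchar(concept$label))
      phi_stop("phi_bad_config", "every theme concept needs a label")
  cfg
}

#' @rdname accessor_config
#' @export
default_theme_concepts <- function() {
  ns <- "http://linkeddata.systems/ConceptSchemes/semanticphi_concept_scheme.rdf#"
  list(
    list(uri = paste0(ns, "BacterialInfectiousAgent"),
         label = "Bacterial Infectious Agent",
         definition = "An infectious agent that is a bacterium."),
    list(uri = paste0(ns, "FungalInfectiousAgent"),
         label = "Fungal Infectious Agent",
         definition = "An infectious agent that is a fungus."),
    list(uri = paste0(ns, "PlantInfectiousDisease"),
         label = "Plant Infectious Disease",
         definition = "A disease of plants caused by an infectious agent.")
  )
}

meta_record_uri <- function(config, token) paste0(config$base_url, "/", token)

#' Emit the repository-level metadata graph
#'
#' One subject -- the accessor URL -- carries every configured facet,
#' the `dcat:theme` pointer to the SKOS concept-scheme document, and the
#' (optionally paginated) list of meta-record URIs.
#'
#' @param config an [accessor_config()].
#' @param interaction_tokens character vector of interaction ID tokens
#'   (e.g. `"INT_00001"`).
#' @param page page number (1-based) when the config sets `page_size`.
#' @return A `phi_triples` graph.
#' @export
repository_metadata <- function(config, interaction_tokens = character(),
                                page = 1L) {
  s <- config$base_url
  ts <- triple_set()
  ts <- ts_add(ts, s, NS$rdf_type,
               c(paste0(NS$prov, "Collection"), paste0(NS$dctypes, "Dataset")))
  ts <- ts_add(ts, s, paste0(NS$dc11, "title"), lit(config$title))
  ts <- add_values(ts, s, paste0(NS$daml, "has-Technical-Lead"),
                   config$technical_leads)
  ts <- add_values(ts, s, paste0(NS$daml, "has-Principle-Investigator"),
                   config$principal_investigators)
  ts <- add_values(ts, s, paste0(NS$pav, "authoredBy"), config$authored_by)
  ts <- add_values(ts, s, paste0(NS$foaf, "page"), config$pages)
  ts <- add_values(ts, s, paste0(NS$dc11, "creator"), config$creator)
  ts <- ts_add(ts, s, paste0(NS$dc11, "issued"), lit(config$issued))
  ts <- add_values(ts, s, paste0(NS$dc11, "language"), config$language_dc)
  ts <- add_values(ts, s, paste0(NS$dcat, "language"), config$language_dcat)
  ts <- add_values(ts, s, paste0(NS$dcat, "license"), config$license)
  ts <- add_values(ts, s, paste0(NS$dcat, "identifier"), config$identifier)
  ts <- add_values(ts, s, paste0(NS$dcat, "keyword"), config$keywords)
  ts <- add_values(ts, s, paste0(NS$dcat, "landingPage"), config$landing_page)
  ts <- ts_add(ts, s, paste0(NS$dcat, "description"),
               lit(config$description))
  ts <- add_values(ts, s, paste0(NS$dcat, "contactPoint"),
                   config$contact_point)
  ts <- add_values(ts, s, paste0(NS$dcat, "publisher"), config$publishers)
  ts <- add_values(ts, s, paste0(NS$dcat, "theme"), config$theme)

  tokens <- interaction_tokens
  if (!is.null(config$page_size) && length(tokens)) {
    n <- config$page_size
    pages <- split(tokens, ceiling(seq_along(tokens) / n))
    page <- max(1L, min(as.integer(page), length(pages)))
    tokens <- pages[[page]]
    if (page < length(pages))
      ts <- ts_add(ts, s, "http://www.w3.org/1999/xhtml/vocab#next",
                   paste0(s, "?page=", page + 1L))
  }
  if (length(tokens))
    ts <- ts_add(ts, s, paste0(NS$ldp, "contains"),
                 vapply(tokens, meta_record_uri, "", config = config))
  ts
}

#' Emit one record-level meta-record
#'
#' The meta-record subject (`<accessor>/<token>`) carries citation and
#' license facets plus exactly two `dcat:distribution` links: the minted
#' interaction URI typed as an RDF (`application/rdf+xml`) distribution
#' with itself as download URL, and the original HTML record page typed
#' `text/html`.
#'
#' @param token interaction ID token, e.g. `"INT_00004"`.
#' @param accession the original record accession, e.g. `"PHI:11"`.
#' @param config an [accessor_config()].
#' @param scheme a [uri_scheme()] (mints the RDF distribution URI).
#' @return A `phi_triples` graph.
#' @export
record_metadata <- function(token, accession, config = accessor_config(),
                            scheme = uri_scheme()) {
  s <- meta_record_uri(config, token)
  rdf_dist <- paste0(scheme$authority, "/", scheme$project, "/",
                     scheme$resolver, "/interaction/", token)
  html_dist <- sprintf(config$record_url_template, accession)
  ts <- triple_set()
  ts <- add_values(ts, s, paste0(NS$dc11, "creator"), config$creator)
  ts <- ts_add(ts, s, paste0(NS$dc11, "issued"), lit(config$issued))
  ts <- add_values(ts, s, paste0(NS$dc11, "license"), config$license)
  ts <- ts_add(ts, s, paste0(NS$dc11, "title"),
               lit(paste0("PHI-Base Interaction PHI:", accession)))
  ts <- add_values(ts, s, paste0(NS$pav, "authoredBy"), config$authored_by)
  ts <- ts_add(ts, s, paste0(NS$void, "inDataset"), config$base_url)
  ts <- add_values(ts, s, paste0(NS$daml, "has-Principle-Investigator"),
                   config$principal_investigators)
  ts <- add_values(ts, s, paste0(NS$daml, "has-Technical-Lead"),
                   config$technical_leads)
  ts <- add_values(ts, s, paste0(NS$dcat, "contactPoint"),
                   config$contact_point)
  ts <- ts_add(ts, s, paste0(NS$dcat, "description"),
               lit(sprintf("RDF representation of PHI Base Interaction Record PHI:%s",
                           accession)))
  ts <- ts_add(ts, s, paste0(NS$dcat, "distribution"), c(rdf_dist, html_dist))
  ts <- add_values(ts, s, paste0(NS$dcat, "identifier"), config$identifier)
  ts <- add_values(ts, s, paste0(NS$dcat, "keyword"), config$record_keywords)
  ts <- add_values(ts, s, paste0(NS$dcat, "landingPage"), config$landing_page)
  ts <- add_values(ts, s, paste0(NS$dcat, "language"), config$language_dcat)
  ts <- add_values(ts, s, paste0(NS$dcat, "license"), config$license)
  ts <- ts_add(ts, s, paste0(NS$dcat, "modified"), lit(config$issued))
  ts <- add_values(ts, s, paste0(NS$dcat, "publisher"), config$publishers)
  ts <- add_values(ts, s, paste0(NS$foaf, "page"), config$landing_page)

  ts <- ts_add(ts, rdf_dist, paste0(NS$dc11, "format"),
               lit("application/rdf+xml"))
  ts <- ts_add(ts, rdf_dist, NS$rdf_type,
               c(paste0(NS$dctypes, "Dataset"), paste0(NS$void, "Dataset"),
                 paste0(NS$dcat, "Distribution")))
  ts <- ts_add(ts, rdf_dist, paste0(NS$dcat, "downloadURL"), rdf_dist)
  ts <- ts_add(ts, html_dist, paste0(NS$dc11, "format"), lit("text/html"))
  ts <- ts_add(ts, html_dist, NS$rdf_type,
               c(paste0(NS$dctypes, "Dataset"), paste0(NS$dcat, "Distribution")))
  ts <- ts_add(ts, html_dist, paste0(NS$dcat, "downloadURL"), html_dist)
  ts
}

#' Emit the SKOS concept scheme backing `dcat:theme`
#'
#' The machine-readable keyword list: each configured concept appears
#' with its URI, one preferred label and one definition.
#'
#' @param config an [accessor_config()].
#' @return A `phi_triples` graph rooted at the concept-scheme URI.
#' @export
concept_scheme <- function(config = accessor_config()) {
  if (length(config$theme_concepts) == 0)
    phi_stop("phi_bad_config", "at least one theme concept is required")
  s <- config$theme
  sk <- function(x) paste0(NS$skos, x)
  ts <- triple_set()
  ts <- ts_add(ts, s, NS$rdf_type, sk("ConceptScheme"))
  ts <- ts_add(ts, s, paste0(NS$dc11, "title"),
               lit(paste(config$title, "concept scheme")))
  for (concept in config$theme_concepts) {
    ts <- ts_add(ts, concept$uri, NS$rdf_type, sk("Concept"))
    ts <- ts_add(ts, concept$uri, sk("prefLabel"), lit(concept$label, "en"))
    if (!is.null(concept$definition))
      ts <- ts_add(ts, concept$uri, sk("definition"),
                   lit(concept$definition, "en"))
    ts <- ts_add(ts, concept$uri, sk("inScheme"), s)
    ts <- ts_add(ts, s, sk("hasTopConcept"), concept$uri)
  }
  ts
}
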