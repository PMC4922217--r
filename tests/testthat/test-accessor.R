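cfg <- accessor_config()

test_that("repository metadata carries every configured facet", {
  g <- repository_metadata(cfg, c("INT_00001", "INT_00002", "INT_00003"))
  df <- as.data.frame(g)
  s <- cfg$base_url
  expect_true(all(df$subject == s))
  types <- df$object[df$predicate == NS_uri("rdf_type")]
  expect_setequal(types, c("http://www.w3.org/ns/prov#Collection",
                           "http://purl.org/dc/dcmitype/Dataset"))
  ttl <- serialize_graph(g, "turtle")
  expect_match(ttl, "http://purl.org/NET/rdflicense/cc-by-nd4.0",
               fixed = TRUE)
  # meta-record list: one per interaction
  members <- df$object[df$predicate == paste0(NS_uri("ldp"), "contains")]
  expect_equal(members, paste0(s, "/INT_0000", 1:3))
  # both language facets are emitted as configured, unreconciled
  expect_true("http://lexvo.org/id/iso639-3/eng" %in% df$object)
  expect_true("http://id.loc.gov/vocabulary/iso639-1/en" %in% df$object)
  # theme points at the concept-scheme document
  expect_true(cfg$theme %in%
                df$object[df$predicate == paste0(NS_uri("dcat"), "theme")])
  # round-trips through Turtle isomorphically
  expect_true(ts_isomorphic(g, parse_graph(ttl, "turtle")))
})

test_that("missing mandatory facets are a config error", {
  expect_error(accessor_config(license = ""), class = "phi_bad_config")
  expect_error(accessor_config(license = "not a uri"),
               class = "phi_bad_config")
  expect_error(accessor_config(theme_concepts = list(list(uri = "http://x"))),
               class = "phi_bad_config")
})

test_that("record metadata reproduces the published layout", {
  g <- record_metadata("INT_00004", "PHI:11", cfg)
  df <- as.data.frame(g)
  s <- paste0(cfg$base_url, "/INT_00004")
  expect_equal(df$object[df$subject == s &
                           df$predicate == paste0(NS_uri("dc11"), "title")],
               "PHI-Base Interaction PHI:PHI:11")
  dists <- df$object[df$subject == s &
                       df$predicate == paste0(NS_uri("dcat"), "distribution")]
  expect_length(dists, 2)
  expect_true("http://www.phi-base.org/query.php?detail=yes&phi_acc=PHI:11"
              %in% dists)
  rdf_dist <- setdiff(dists,
                      "http://www.phi-base.org/query.php?detail=yes&phi_acc=PHI:11")
  expect_equal(rdf_dist,
    "http://linkeddata.systems/SemanticPHIBase/Resource/interaction/INT_00004")
  # media types as printed, one RDF + one HTML
  fmts <- df[df$predicate == paste0(NS_uri("dc11"), "format"), ]
  expect_setequal(fmts$object, c("application/rdf+xml", "text/html"))
  # each distribution is its own download URL
  for (d in dists)
    expect_equal(df$object[df$subject == d &
                             df$predicate == paste0(NS_uri("dcat"), "downloadURL")],
                 d)
  expect_true(cfg$base_url %in%
                df$object[df$predicate == paste0(NS_uri("void"), "inDataset")])
})

test_that("every fixture interaction gets a meta-record with 2 distributions", {
  tr <- phi_small_transform()
  for (i in seq_len(nrow(tr$interactions))) {
    g <- record_metadata(tr$interactions$token[i],
                         tr$interactions$accession[i], cfg)
    dists <- g$object[g$predicate == paste0(NS_uri("dcat"), "distribution")]
    expect_length(dists, 2)
  }
})

test_that("the SKOS concept scheme lists labeled, defined concepts", {
  g <- concept_scheme(cfg)
  df <- as.data.frame(g)
  skos <- NS_uri("skos")
  expect_true(any(df$object == paste0(skos, "ConceptScheme")))
  concepts <- df$subject[df$predicate == NS_uri("rdf_type") &
                           df$object == paste0(skos, "Concept")]
  expect_true(length(concepts) >= 1)
  labels <- df$object[df$predicate == paste0(skos, "prefLabel")]
  expect_true("Plant Infectious Disease" %in% labels)
  for (concept in concepts) {
    expect_length(df$object[df$subject == concept &
                              df$predicate == paste0(skos, "prefLabel")], 1)
    expect_length(df$object[df$subject == concept &
                              df$predicate == paste0(skos, "definition")], 1)
  }
})

test_that("pagination is off by default and pages when configured", {
  toks <- sprintf("INT_%05d", 1:7)
  g0 <- repository_metadata(cfg, toks)
  expect_length(g0$object[g0$predicate == paste0(NS_uri("ldp"), "contains")], 7)
  cfg_p <- accessor_config(page_size = 3)
  g1 <- repository_metadata(cfg_p, toks, page = 1)
  expect_length(g1$object[g1$predicate == paste0(NS_uri("ldp"), "contains")], 3)
  expect_true(any(grepl("page=2", g1$object)))
  g3 <- repository_metadata(cfg_p, toks, page = 3)
  expect_length(g3$object[g3$predicate == paste0(NS_uri("ldp"), "contains")], 1)
  expect_false(any(grepl("page=", g3$object[!g3$is_literal])))
})
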