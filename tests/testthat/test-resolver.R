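svc <- NULL
setup_svc <- function() {
  if (is.null(svc)) svc <<- phi_service(phi_small_transform(),
                                        accessor_config())
  svc
}

test_that("describe returns exactly the subject-position statements", {
  tr <- phi_small_transform()
  uri <- tr$interactions$uri[1]
  sub <- describe_entity(uri, tr$graph)
  expect_true(all(sub$statements$subject == uri))
  expect_true(any(sub$statements$predicate == NS_uri("rdfs_label")))
  expect_error(describe_entity("http://nowhere/x", tr$graph),
               class = "phi_not_found")
  # union of describes covers all minted-subject statements
  minted <- unique(tr$graph$subject[is_minted_uri(tr$graph$subject)])
  union <- do.call(phifair:::ts_rbind,
                   lapply(minted, function(u)
                     describe_entity(u, tr$graph)$statements))
  minted_stmts <- tr$graph[tr$graph$subject %in% minted, ]
  expect_equal(nrow(ts_unique(union)),
               nrow(ts_unique(structure(as.data.frame(minted_stmts),
                                        class = class(tr$graph)))))
  # inbound statements only behind the flag
  sub_in <- describe_entity(uri, tr$graph, include_inbound = TRUE)
  expect_true(nrow(sub_in$statements) >= nrow(sub$statements))
})

test_that("HTML rendering shows every statement, links URIs, texts literals", {
  tr <- phi_small_transform()
  sub <- describe_entity(tr$interactions$uri[1], tr$graph)
  html <- render_html(sub)
  expect_equal(lengths(regmatches(html, gregexpr("<h3>", html, fixed = TRUE))),
               nrow(sub$statements))
  # label is the page title
  lab <- sub$statements$object[sub$statements$predicate == NS_uri("rdfs_label")]
  expect_match(html, paste0("<title>", lab), fixed = TRUE)
  # literals are not wrapped in anchors; URIs are
  desc_sub <- describe_entity(
    tr$graph$subject[tr$graph$predicate ==
                       model_vocabulary()$has_value][1], tr$graph)
  dhtml <- render_html(desc_sub)
  litval <- desc_sub$statements$object[desc_sub$statements$is_literal &
    desc_sub$statements$predicate == model_vocabulary()$has_value][1]
  expect_match(dhtml, litval, fixed = TRUE)
  expect_false(grepl(paste0(">", litval, "</a>"), dhtml, fixed = TRUE))
  uris <- sub$statements$object[!sub$statements$is_literal]
  expect_match(html, paste0("<a href=\"", uris[1], "\""), fixed = TRUE)
})

test_that("content negotiation serves HTML and RDF from one subgraph", {
  s <- setup_svc()
  path <- "/SemanticPHIBase/Resource/interaction/INT_00001"
  h <- resolve_request(s, path, "text/html")
  r <- resolve_request(s, path, "application/rdf+xml")
  t <- resolve_request(s, path, "text/turtle")
  expect_equal(h$status, 200L); expect_equal(h$content_type, "text/html")
  expect_equal(r$status, 200L)
  expect_equal(r$content_type, "application/rdf+xml")
  sub <- describe_entity(paste0("http://linkeddata.systems", path),
                         s$store)
  expect_true(ts_isomorphic(parse_graph(r$body, "rdfxml"), sub$statements))
  expect_true(ts_isomorphic(parse_graph(t$body, "turtle"), sub$statements))
  # browser-style and unrecognized-but-wildcard Accept default to HTML
  expect_equal(resolve_request(s, path,
    "text/html,application/xhtml+xml,*/*;q=0.8")$content_type, "text/html")
  expect_equal(resolve_request(s, path, "image/png,*/*")$content_type,
               "text/html")
  # full URL is accepted in place of a bare path
  expect_equal(resolve_request(s, paste0("http://linkeddata.systems", path),
                               "text/html")$status, 200L)
})

test_that("metadata endpoints and concept scheme resolve through the service", {
  s <- setup_svc()
  m <- resolve_request(s, "/SemanticPHIBase/Metadata", "text/turtle")
  expect_equal(m$status, 200L)
  g <- parse_graph(m$body, "turtle")
  expect_true(all(g$subject == accessor_config()$base_url))
  mr <- resolve_request(s, "/SemanticPHIBase/Metadata/INT_00002",
                        "text/turtle")
  expect_equal(mr$status, 200L)
  expect_match(mr$body, "INT_00002", fixed = TRUE)
  cs <- resolve_request(s, "/ConceptSchemes/semanticphi_concept_scheme.rdf",
                        "text/turtle")
  expect_equal(cs$status, 200L)
  expect_true(ts_isomorphic(
    describe_entity(accessor_config()$theme, concept_scheme(accessor_config()))$statements,
    parse_graph(cs$body, "turtle")))
})

test_that("unknown URIs 404, unacceptable media 406", {
  s <- setup_svc()
  expect_equal(resolve_request(s, "/SemanticPHIBase/Resource/interaction/INT_99999",
                               "text/html")$status, 404L)
  expect_equal(resolve_request(s, "/elsewhere", "text/html")$status, 404L)
  expect_equal(resolve_request(s, "/SemanticPHIBase/Metadata/INT_99999",
                               "text/html")$status, 404L)
  expect_equal(resolve_request(s, "/SemanticPHIBase/Resource/interaction/INT_00001",
                               "application/json")$status, 406L)
})

test_that("stylesheet-compat mode emits the processing instruction", {
  s <- phi_service(phi_small_transform(), accessor_config(),
                   stylesheet_compat = TRUE)
  r <- resolve_request(s, "/SemanticPHIBase/Resource/interaction/INT_00001",
                       "application/rdf+xml")
  expect_match(r$body, "<\\?xml-stylesheet type=\"text/xsl\"")
  expect_match(r$body, "styles/phi.xsl", fixed = TRUE)
  # the PI does not disturb parsing
  sub <- describe_entity(
    "http://linkeddata.systems/SemanticPHIBase/Resource/interaction/INT_00001",
    s$store)
  expect_true(ts_isomorphic(parse_graph(r$body, "rdfxml"), sub$statements))
})

test_that("static publication writes the full resource tree", {
  dir <- withr::local_tempdir()
  files <- accessor_static(setup_svc(), dir)
  expect_true(file.exists(file.path(dir, "data.nq")))
  expect_true(file.exists(file.path(dir, "Metadata.ttl")))
  expect_true(file.exists(file.path(dir, "concept_scheme.ttl")))
  toks <- phi_small_transform()$interactions$token
  expect_true(all(file.exists(file.path(dir, paste0("Metadata_", toks, ".ttl")))))
  expect_true(all(file.exists(file.path(dir, paste0(toks, ".html")))))
})
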