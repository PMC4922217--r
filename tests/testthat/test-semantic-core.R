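vocab <- model_vocabulary()

test_that("a record graph has the Figure-style interaction shape", {
  tabs <- default_mapping_tables()
  g <- build_record_graph(reference_record(), tabs)
  df <- as.data.frame(g)
  int <- df$subject[df$predicate == NS_uri("rdf_type") &
                      df$object == vocab$cls_interaction]
  expect_length(int, 1)
  # exactly two participants, one host + one pathogen
  parts <- df$object[df$subject == int & df$predicate == vocab$has_participant]
  expect_length(parts, 2)
  types <- df$object[df$subject %in% parts &
                       df$predicate == NS_uri("rdf_type")]
  expect_true(vocab$cls_host %in% types && vocab$cls_pathogen %in% types)
  # exactly two interaction contexts via is_manifested_as
  ctxs <- df$object[df$subject == int & df$predicate == vocab$is_manifested_as]
  expect_length(ctxs, 2)
  # each context depends on a host and a pathogen context
  for (cx in ctxs)
    expect_length(df$object[df$subject == cx &
                              df$predicate == vocab$depends_on], 2)
  # base state: a description with literal "BASE STATE"
  base_desc <- df$subject[df$predicate == vocab$has_value &
                            df$is_literal & df$object == "BASE STATE"]
  expect_length(base_desc, 1)
  # one pathogen context typed wild-type genotype
  expect_length(df$subject[df$predicate == NS_uri("rdf_type") &
                             df$object == vocab$ext_wild_type_genotype], 1)
  # allele -> gene -> organism chain
  allele <- df$subject[df$predicate == vocab$variant_of]
  expect_length(allele, 1)
  gene <- df$object[df$predicate == vocab$variant_of]
  org <- df$object[df$subject == gene &
                     df$predicate == vocab$is_proper_part_of]
  expect_equal(org, "http://identifiers.org/taxonomy/318829")
  # organism carries the four external types plus role labels
  org_types <- df$object[df$subject == org & df$predicate == NS_uri("rdf_type")]
  expect_true(all(c(vocab$ext_pathogen, vocab$ext_organism) %in% org_types))
  # UniProt xref typed with the EDAM UniProt accession concept
  expect_true(any(df$subject == "http://identifiers.org/uniprot/P22287" &
                    df$predicate == NS_uri("rdf_type") &
                    df$object == "http://edamontology.org/data_3021"))
  # PubMed identifier reachable from the citation
  cit <- df$object[df$predicate == vocab$citation]
  expect_equal(df$object[df$subject == cit &
                           df$predicate == vocab$has_unique_identifier],
               "http://identifiers.org/pubmed/1234567")
})

test_that("same gene in two records converges on one Gene, distinct alleles", {
  tabs <- default_mapping_tables()
  mk <- function(acc) interaction_record(
    acc, "Magnaporthe oryzae", "Rice", "Reduced virulence",
    gene_name = "PMK1", literature_ids = "1")
  counters <- serial_counters()
  g1 <- build_record_graph(mk("PHI:1"), tabs, counters = counters)
  g2 <- build_record_graph(mk("PHI:2"), tabs, counters = counters)
  m <- merge_shared_nodes(list(g1, g2))
  df <- as.data.frame(m)
  genes <- unique(df$object[df$predicate == vocab$variant_of])
  expect_length(genes, 1)
  alleles <- unique(df$subject[df$predicate == vocab$variant_of])
  expect_length(alleles, 2)
  # merged gene keeps exactly one label
  expect_equal(sum(df$subject == genes & df$predicate == NS_uri("rdfs_label")), 1)
  # organisms deduplicate by taxon URI
  orgs <- unique(df$object[df$predicate == vocab$is_member_of])
  expect_length(orgs, 2)  # one pathogen + one host taxon

  # different species stay apart
  g3 <- build_record_graph(
    interaction_record("PHI:3", "Botrytis cinerea", "Tomato",
                       "Reduced virulence", gene_name = "PMK1"),
    tabs, counters = counters)
  m2 <- merge_shared_nodes(list(g1, g3))
  expect_length(unique(as.data.frame(m2)$object[
    m2$predicate == vocab$variant_of]), 2)
  # merge of a single graph is the identity
  expect_true(ts_isomorphic(merge_shared_nodes(list(g1)), g1))
})

test_that("transform is deterministic and orders records by accession", {
  fx <- phi_small_fixture()
  tr1 <- transform_records(fx$records, fx$tables)
  tr2 <- transform_records(rev(fx$records), fx$tables)
  expect_identical(serialize_graph(tr1$graph, "turtle"),
                   serialize_graph(tr2$graph, "turtle"))
  expect_identical(tr1$interactions, tr2$interactions)
  expect_equal(tr1$interactions$accession,
               sort(tr1$interactions$accession, method = "radix"))
  expect_equal(tr1$interactions$token,
               sprintf("INT_%05d", seq_len(nrow(tr1$interactions))))
})

test_that("transformed fixtures validate cleanly", {
  rep <- validate_graph(phi_small_transform()$graph, vocab)
  expect_equal(nrow(rep), 0)
  expect_s3_class(rep, "phi_validation")
  # convention-based placements are noted, not violations
  expect_true(nrow(attr(rep, "notes")) > 0)
})

test_that("validator catches shape violations", {
  g <- phi_reference_transform()$graph
  # literal via an ad-hoc predicate
  bad1 <- ts_add(g, mint_uri("interaction", 1),
                 "http://example.org/has_description", lit("sneaky"))
  expect_true(any(validate_graph(bad1, vocab)$rule == "has_value"))
  # unlabeled minted node
  bad2 <- ts_add(g, mint_uri("description", 999),
                 NS_uri("rdf_type"), vocab$cls_description)
  r2 <- validate_graph(bad2, vocab)
  expect_true(any(r2$rule == "label"))
  # label without a language tag
  bad3 <- ts_rbind(g, triple_set(rep(mint_uri("quality", 999), 2),
                                 c(NS_uri("rdf_type"), NS_uri("rdfs_label")),
                                 c(vocab$cls_strain, "untagged"),
                                 c(FALSE, TRUE)))
  expect_true(any(validate_graph(bad3, vocab)$rule == "label"))
  # untyped has_unique_identifier object
  bad4 <- ts_add(g, mint_uri("gene", 1), vocab$has_unique_identifier,
                 "http://identifiers.org/uniprot/Q00000")
  expect_true(any(validate_graph(bad4, vocab)$rule == "identifier_typed"))
  # minted-grammar violation
  bad5 <- ts_add(g, mint_uri("interaction", 1), NS_uri("rdfs_seealso"),
    "http://linkeddata.systems/SemanticPHIBase/Resource/interaction/INT_1")
  expect_true(any(validate_graph(bad5, vocab)$rule == "uri_grammar"))
})

test_that("every populated input field is conserved in the graph", {
  fx <- phi_small_fixture()
  tr <- phi_small_transform()
  cov <- field_coverage(fx$records, tr$graph, fx$tables)
  expect_true(all(cov$covered))
  # and external concepts are Identifiers.org URIs
  df <- as.data.frame(tr$graph)
  xrefs <- df$object[df$predicate == vocab$has_unique_identifier &
                       !df$is_literal & !is_minted_uri(df$object)]
  expect_true(all(startsWith(xrefs, "http://identifiers.org/")))
})

test_that("unknown DbType drops the cross-reference but keeps the record", {
  tabs <- default_mapping_tables()
  rec <- interaction_record("PHI:77", "Magnaporthe oryzae", "Rice",
                            "Reduced virulence", db_type = "NO_SUCH_DB",
                            accession = "A1")
  tr <- transform_records(list(rec), tabs)
  expect_equal(nrow(tr$interactions), 1)
  expect_true(any(tr$unmapped$domain == "dbtype"))
  expect_false(any(grepl("A1", tr$graph$object[!tr$graph$is_literal],
                         fixed = TRUE)))
})

test_that("the shipped ontology declares every model predicate with a mirror", {
  og <- ontology_graph(vocab)
  df <- as.data.frame(og)
  preds <- c(vocab$has_participant, vocab$depends_on, vocab$is_manifested_as,
             vocab$is_member_of, vocab$is_proper_part_of, vocab$variant_of,
             vocab$has_quality, vocab$has_unique_identifier, vocab$has_value,
             vocab$is_output_of)
  for (p in preds) {
    expect_true(any(df$subject == p & df$predicate == NS_uri("rdfs_subprop")),
                label = p)
    expect_true(any(df$subject == p & df$predicate == NS_uri("rdfs_label")))
  }
})
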