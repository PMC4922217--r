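phen_df <- function() data.frame(
  raw = c("Reduced virulence", "reduced virulence", "Increased virulence"),
  canonical_label = c("Reduced virulence", "Reduced virulence",
                      "Increased virulence"),
  uri = c("http://example.org/onto#RV", "http://example.org/onto#RV",
          "http://example.org/onto#IV"),
  stringsAsFactors = FALSE)

test_that("case/punctuation variants of one term share one URI", {
  tab <- mapping_table(phen_df(), "phenotype")
  u1 <- harmonize_term("Reduced virulence", tab)$uri
  for (variant in c("reduced virulence", "REDUCED VIRULENCE",
                    "Reduced  virulence", "reduced virulence.",
                    "Reduced Virulence,", " reduced   virulence;"))
    expect_equal(harmonize_term(variant, tab)$uri, u1)
  # identity case: a canonical label maps to its own term
  term <- harmonize_term("Increased virulence", tab)
  expect_equal(term$uri, "http://example.org/onto#IV")
  expect_equal(as.character(term$label), "Increased virulence")
  expect_equal(attr(term$label, "lang"), "en")
})

test_that("harmonization is idempotent", {
  tab <- mapping_table(phen_df(), "phenotype")
  for (raw in c("reduced virulence.", "INCREASED VIRULENCE")) {
    once <- harmonize_term(raw, tab)
    twice <- harmonize_term(unclass(once$label), tab)
    expect_equal(twice$uri, once$uri)
  }
})

test_that("conflicting duplicate keys are rejected; empty tables miss everything", {
  bad <- phen_df()
  bad$uri[2] <- "http://example.org/onto#OTHER"
  expect_error(mapping_table(bad, "phenotype"),
               class = "phi_conflicting_mapping")
  empty <- mapping_table(phen_df()[0, ], "phenotype")
  expect_error(harmonize_term("anything", empty),
               class = "phi_unmapped_term")
})

test_that("strict misses error; mint policy coins stable URIs and reports", {
  tab <- mapping_table(phen_df(), "phenotype")
  err <- tryCatch(harmonize_term("novel phenotype", tab),
                  phi_unmapped_term = identity)
  expect_s3_class(err, "phi_unmapped_term")
  expect_equal(err$raw, "novel phenotype")
  expect_equal(err$domain, "phenotype")

  col <- unmapped_collector()
  m1 <- harmonize_term("Novel  Phenotype.", tab, policy = "mint",
                       collector = col)
  m2 <- harmonize_term("novel phenotype", tab, policy = "mint",
                       collector = col)
  expect_equal(m1$uri, m2$uri)  # stable across calls and perturbations
  expect_true(startsWith(m1$uri,
                         "http://linkeddata.systems/ontologies/SemanticPHIBase#"))
  rep <- unmapped_report(col)
  expect_equal(sum(rep$count), 2)
})

test_that("mapping tables load from TSV and reject malformed URIs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(phen_df(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- load_mapping_table(path, "phenotype")
  expect_equal(harmonize_term("reduced virulence", tab)$uri,
               "http://example.org/onto#RV")
  bad <- phen_df(); bad$uri[3] <- "not a uri"
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_mapping_table(path, "phenotype"),
               class = "phi_bad_table")
})

test_that("species mapping resolves common names, keeps rank and taxon URI", {
  tab <- default_mapping_tables()$species
  rice <- map_species("Rice", tab)
  expect_equal(rice$scientific_name, "Oryza sativa")
  expect_equal(rice$common_name, "Rice")
  expect_equal(rice$taxon_id, 4530L)
  expect_equal(rice$taxon_uri, "http://identifiers.org/taxonomy/4530")
  # binomial already in the table maps to itself at species rank
  mo <- map_species("Magnaporthe oryzae", tab)
  expect_equal(mo$scientific_name, "Magnaporthe oryzae")
  expect_equal(mo$rank, "species")
  # genus-only resolution is allowed
  fg <- map_species("fusarium", tab)
  expect_equal(fg$rank, "genus")
  expect_equal(fg$taxon_id, 5506L)
  expect_error(map_species("Martian weed", tab),
               class = "phi_unmapped_term")
})

test_that("cross-references build Identifiers.org URIs with EDAM types", {
  tab <- default_mapping_tables()$dbtype
  x <- xref_to_uri("ENTREZ PROTEIN", "X12345", tab)
  expect_equal(x$uri, "http://identifiers.org/ena.embl/X12345")
  u <- xref_to_uri("UNIPROT", "P22287", tab)
  expect_equal(u$uri, "http://identifiers.org/uniprot/P22287")
  expect_equal(u$edam_type, "http://edamontology.org/data_3021")
  expect_error(xref_to_uri("NO_SUCH_DB", "A1", tab),
               class = "phi_unmapped_term")
  # invariant: prefix + accession, exactly
  expect_true(startsWith(x$uri, "http://identifiers.org/ena.embl/"))
  expect_true(endsWith(x$uri, x$raw_accession))
})

test_that("disease names resolve to DBpedia or a stable local URI", {
  tab <- default_mapping_tables()$disease
  expect_equal(disease_to_uri("Rice blast", tab),
               "http://dbpedia.org/resource/Rice_blast")
  u1 <- disease_to_uri("Mystery wilt", tab)
  expect_equal(disease_to_uri("Mystery wilt", tab), u1)  # deterministic
  expect_true(startsWith(u1, uri_scheme()$ontology_ns))
  u2 <- disease_to_uri("Other rot", tab)
  expect_false(u1 == u2)  # distinct names, distinct URIs
})
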