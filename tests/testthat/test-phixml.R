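test_that("parsing preserves document order, cardinality and field values", {
  recs <- list(
    interaction_record("PHI:3", "Magnaporthe oryzae", "Rice",
                       "reduced virulence"),
    interaction_record("PHI:1", "Fusarium graminearum", "Wheat",
                       "Loss of pathogenicity",
                       go_annotations = c("GO:0000001", "GO:0000002"),
                       literature_ids = "123"),
    interaction_record("PHI:2", "Botrytis cinerea", "Tomato", "Lethal")
  )
  xml <- write_phibase_xml(recs)
  back <- parse_phibase_xml(xml)
  expect_length(back, 3)
  expect_equal(vapply(back, `[[`, "", "phibase_accession"),
               c("PHI:3", "PHI:1", "PHI:2"))  # document order, not sorted
  expect_equal(back[[1]]$phenotype_of_mutant, "reduced virulence")
  expect_equal(back[[2]]$go_annotations, c("GO:0000001", "GO:0000002"))
})

test_that("parser strips surrounding whitespace and tolerates unknown tags", {
  xml <- paste0(
    "<Records><Record><PHI-base_accession>  PHI:9 </PHI-base_accession>",
    "<Mystery_tag>ignored</Mystery_tag>",
    "<Pathogen_species>Magnaporthe oryzae</Pathogen_species>",
    "<Experimental_host>Rice</Experimental_host>",
    "<Phenotype_of_mutant>\n  reduced virulence\n</Phenotype_of_mutant>",
    "</Record></Records>")
  rec <- parse_phibase_xml(xml)[[1]]
  expect_equal(rec$phibase_accession, "PHI:9")
  expect_equal(rec$phenotype_of_mutant, "reduced virulence")
  expect_null(rec$gene_name)
})

test_that("malformed XML and duplicate accessions are rejected", {
  expect_error(parse_phibase_xml("<Records><Record>"),
               class = "phi_parse_error")
  xml <- write_phibase_xml(list(
    interaction_record("PHI:1", "a b", "c d", "x"),
    interaction_record("PHI:1", "a b", "c d", "y")))
  expect_error(parse_phibase_xml(xml), class = "phi_duplicate_accession")
})

test_that("record invariants are enforced", {
  expect_error(interaction_record("", "a", "b", "c"),
               class = "phi_invalid_record")
  expect_error(interaction_record("PHI:1", "a", "b", "c", host_taxid = -4),
               class = "phi_invalid_record")
  expect_error(interaction_record("PHI:1", "a", "b", "c",
                                  aa_sequence = "MA8!"),
               class = "phi_invalid_record")
  expect_error(interaction_record("PHI:1", "a", "b", "c",
                                  nt_sequence = "ACGTQ"),
               class = "phi_invalid_record")
  # whitespace and case in sequences are tolerated (cleaned before check)
  r <- interaction_record("PHI:1", "a", "b", "c",
                          aa_sequence = "ma crv\nwy")
  expect_equal(r$aa_sequence, "ma crv\nwy")
})

test_that("round-trip preserves every field across randomized fixtures", {
  for (seed in c(1, 2)) {
    fx <- generate_fixture(fixture_spec(10, seed = seed))
    xml <- write_phibase_xml(fx$records)
    back <- parse_phibase_xml(xml)
    expect_equal(back, fx$records)
    # write(parse(write(parse(x)))) is byte-identical (idempotence)
    expect_identical(write_phibase_xml(back), xml)
  }
})

test_that("empty record set yields a valid empty document", {
  xml <- write_phibase_xml(list())
  expect_length(parse_phibase_xml(xml), 0)
})

test_that("host filtering keeps allowlisted hosts, reports the rest", {
  fx <- generate_fixture(fixture_spec(5, seed = 4, n_animal_records = 2))
  recs <- fx$records
  kept <- filter_records(recs, taxon_ids = fx$allowlist$taxon_id)
  expect_length(kept, 5)
  expect_equal(nrow(attr(kept, "excluded")), 2)
  # order preserved and result is a subset
  expect_true(all(vapply(kept, `[[`, "", "phibase_accession") %in%
                    vapply(recs, `[[`, "", "phibase_accession")))
  # name-pattern route matches too (on a fixture without common names,
  # since patterns match the raw experimental_host text)
  fx0 <- generate_fixture(fixture_spec(
    5, seed = 4, messiness = list(case = 0.5, punct = 0, common = 0,
                                  missing = 0.2), n_animal_records = 2))
  kept2 <- filter_records(fx0$records,
                          name_patterns = fx0$allowlist$name_pattern)
  expect_length(kept2, 5)
  # identity when everything matches
  all_ids <- vapply(recs, `[[`, 1L, "host_taxid")
  expect_length(filter_records(recs, taxon_ids = all_ids), 7)
  expect_error(filter_records(recs), class = "phi_empty_allowlist")
})

test_that("allowlist TSV round-trips through read_allowlist", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(3, seed = 5), dir = dir)
  al <- read_allowlist(file.path(dir, "allowlist.tsv"))
  expect_setequal(al$taxon_ids, fx$allowlist$taxon_id)
  expect_setequal(al$name_patterns, fx$allowlist$name_pattern)
})
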