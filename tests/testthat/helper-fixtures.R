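# Shared fixture state, built once per test run.  The "messy" fixture is
# the acceptance-scale dataset (50 records, all messiness probabilities
# at 0.5); the small fixture keeps unit tests fast.

phi_messy_spec <- function() {
  fixture_spec(50, seed = 42,
               messiness = list(case = 0.5, punct = 0.5, common = 0.5,
                                missing = 0.5))
}

phi_cache <- new.env(parent = emptyenv())

phi_fixture <- function() {
  if (is.null(phi_cache$fx))
    phi_cache$fx <- generate_fixture(phi_messy_spec())
  phi_cache$fx
}

phi_transform <- function() {
  if (is.null(phi_cache$tr))
    phi_cache$tr <- transform_records(phi_fixture()$records,
                                      phi_fixture()$tables,
                                      named_graph = accessor_config()$base_url)
  phi_cache$tr
}

phi_small_fixture <- function() {
  if (is.null(phi_cache$sfx))
    phi_cache$sfx <- generate_fixture(fixture_spec(8, seed = 11))
  phi_cache$sfx
}

phi_small_transform <- function() {
  if (is.null(phi_cache$str))
    phi_cache$str <- transform_records(phi_small_fixture()$records,
                                       phi_small_fixture()$tables,
                                       named_graph = accessor_config()$base_url)
  phi_cache$str
}

phi_reference_transform <- function() {
  if (is.null(phi_cache$ref))
    phi_cache$ref <- transform_records(list(reference_record()),
                                       default_mapping_tables(),
                                       named_graph = accessor_config()$base_url)
  phi_cache$ref
}

NS_uri <- function(key) phifair:::NS[[key]]

# organism label as the graph builder composes it
phi_org_label <- function(scientific) {
  taxa <- phifair:::fixture_taxa()
  row <- taxa[taxa$scientific_name == scientific, ]
  if (nzchar(row$common_name))
    sprintf("%s (%s)", row$scientific_name, row$common_name)
  else row$scientific_name
}
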