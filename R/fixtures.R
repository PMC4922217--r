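# Synthetic fixtures ---------------------------------------------------------
#
# Generates dump-shaped XML plus the companion curated mapping tables,
# emulating the real dump's defects: inconsistent capitalization and
# punctuation of descriptive terms, occasional organism common-names,
# and sparsely populated optional fields.  Every perturbation stays
# within reach of the harmonization normalization rule, and the emitted
# tables are complete for everything generated, so a strict-mode
# transformation of a fixture must succeed and reproduce the ground-
# truth manifest exactly.

fixture_taxa <- function() {
  data.frame(
    scientific_name = c("Magnaporthe oryzae", "Fusarium graminearum",
                        "Botrytis cinerea", "Ustilago maydis",
                        "Phytophthora infestans", "Fusarium",
                        "Oryza sativa", "Triticum aestivum", "Zea mays",
                        "Solanum lycopersicum", "Hordeum vulgare",
                        "Arabidopsis thaliana",
                        "Mus musculus", "Homo sapiens"),
    common_name = c("Rice blast fungus", "", "Grey mould fungus",
                    "Corn smut fungus", "", "",
                    "Rice", "Wheat", "Maize", "Tomato", "Barley",
                    "Thale cress", "Mouse", "Human"),
    taxon_id = c(318829L, 5518L, 40559L, 5270L, 4787L, 5506L,
                 4530L, 4565L, 4577L, 4081L, 4513L, 3702L,
                 10090L, 9606L),
    rank = c("species", "species", "species", "species", "species",
             "genus", rep("species", 8)),
    role = c(rep("pathogen", 6), rep("plant_host", 6),
             rep("animal_host", 2)),
    stringsAsFactors = FALSE
  )
}

fixture_terms <- function(ontology_ns) {
  mk <- function(domain, labels) {
    data.frame(raw = labels, canonical_label = labels,
               uri = paste0(ontology_ns, toupper(substr(domain, 1, 4)), "_",
                            vapply(labels, slugify, "")),
               stringsAsFactors = FALSE)
  }
  list(
    phenotype = mk("phenotype",
                   c("Reduced virulence", "Increased virulence",
                     "Loss of pathogenicity", "Unaffected pathogenicity",
                     "Lethal")),
    evidence = mk("evidence",
                  c("Gene disruption", "Gene deletion",
                    "Gene complementation", "RNA interference")),
    in_vitro_growth = mk("in_vitro_growth",
                         c("Normal growth", "Reduced growth", "No change"))
  )
}

fixture_dbtypes <- function() {
  data.frame(
    raw = c("UNIPROT", "ENTREZ PROTEIN", "EMBL"),
    prefix = c("http://identifiers.org/uniprot/",
               "http://identifiers.org/ena.embl/",
               "http://identifiers.org/ena.embl/"),
    edam_uri = c("http://edamontology.org/data_3021",
                 "http://edamontology.org/data_2907",
                 "http://edamontology.org/data_2907"),
    stringsAsFactors = FALSE
  )
}

fixture_diseases <- function() {
  data.frame(
    raw = c("Rice blast", "Head blight", "Late blight"),
    uri = c("http://dbpedia.org/resource/Rice_blast",
            "http://dbpedia.org/resource/Fusarium_ear_blight",
            "http://dbpedia.org/resource/Phytophthora_infestans"),
    stringsAsFactors = FALSE
  )
}

#' The default curated mapping tables
#'
#' Covers the fixture taxa/term pools and the worked-example reference
#' record.  These tables emulate the hand-built curation tables of a
#' real deployment; they are synthetic except for well-known organism
#' names and taxon IDs.
#'
#' @param scheme a [uri_scheme()] (supplies the vocabulary namespace).
#' @return Named list of [mapping_table()]s, one per domain.
#' @export
default_mapping_tables <- function(scheme = uri_scheme()) {
  taxa <- fixture_taxa()
  # table rows keyed both by scientific and by common name
  sp <- data.frame(raw = taxa$scientific_name,
                   scientific_name = taxa$scientific_name,
                   taxon_id = taxa$taxon_id, rank = taxa$rank,
                   common_name = taxa$common_name, stringsAsFactors = FALSE)
  has_common <- nzchar(taxa$common_name)
  sp <- rbind(sp, data.frame(raw = taxa$common_name[has_common],
                             scientific_name = taxa$scientific_name[has_common],
                             taxon_id = taxa$taxon_id[has_common],
                             rank = taxa$rank[has_common],
                             common_name = taxa$common_name[has_common],
                             stringsAsFactors = FALSE))
  terms <- fixture_terms(scheme$ontology_ns)
  list(
    species = mapping_table(sp, "species"),
    phenotype = mapping_table(terms$phenotype, "phenotype"),
    evidence = mapping_table(terms$evidence, "evidence"),
    in_vitro_growth = mapping_table(terms$in_vitro_growth, "in_vitro_growth"),
    dbtype = mapping_table(fixture_dbtypes(), "dbtype"),
    disease = mapping_table(fixture_diseases(), "disease")
  )
}

#' Specify a synthetic fixture
#'
#' @param n_records number of plant-host interaction records.
#' @param seed integer seed; the same spec always produces byte-identical
#'   output.
#' @param messiness named list of probabilities in `[0,1]`:
#'   `case` (case perturbation of descriptive terms and names),
#'   `punct` (trailing-punctuation / internal-whitespace perturbation),
#'   `common` (organism referred to by common name), and
#'   `missing` (each optional field left unpopulated).
#' @param n_animal_records extra records with animal hosts (for
#'   host-filtering tests); default 0.
#' @return A `phi_fixture_spec`.
#' @export
fixture_spec <- function(n_records = 50L, seed = 1L,
                         messiness = list(case = 0.3, punct = 0.3,
                                          common = 0.3, missing = 0.2),
                         n_animal_records = 0L) {
  for (p in c("case", "punct", "common", "missing")) {
    v <- messiness[[p]]
    if (is.null(v) || is.na(v) || v < 0 || v > 1)
      phi_stop("phi_bad_config",
               sprintf("messiness$%s must be a probability in [0,1]", p))
  }
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 messiness = messiness,
                 n_animal_records = as.integer(n_animal_records)),
            class = "phi_fixture_spec")
}

perturb_case <- function(x) {
  chars <- strsplit(x, "")[[1]]
  flip <- stats::runif(length(chars)) < 0.5
  chars[flip] <- ifelse(chars[flip] == toupper(chars[flip]),
                        tolower(chars[flip]), toupper(chars[flip]))
  paste(chars, collapse = "")
}

perturb_punct <- function(x) {
  style <- sample(c("trail_dot", "trail_comma", "double_space"), 1)
  switch(style,
    trail_dot = paste0(x, "."),
    trail_comma = paste0(x, ","),
    double_space = if (grepl(" ", x, fixed = TRUE))
      sub(" ", "  ", x, fixed = TRUE) else paste0(x, ";"))
}

#' Generate a synthetic dump plus companion tables and ground truth
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, writes `records.xml`, one
#'   `<domain>.tsv` per mapping table, `manifest.tsv` and
#'   `allowlist.tsv` there.
#' @param scheme a [uri_scheme()].
#' @return Invisible list: `records` (parsed `phi_record`s), `xml`
#'   (document text), `tables` (the mapping tables), `manifest` (ground
#'   truth data frame: intended canonical terms and taxa per record),
#'   `allowlist` (plant-host allowlist data frame).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL,
                             scheme = uri_scheme()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  taxa <- fixture_taxa()
  terms <- fixture_terms(scheme$ontology_ns)
  dbtypes <- fixture_dbtypes()
  diseases <- fixture_diseases()
  tables <- default_mapping_tables(scheme)
  m <- spec$messiness

  gene_pool <- c("PMK1", "MPS1", "TRI5", "BMP1", "CPKA", "UBC3", "MAC1",
                 "NPR1", "ABC1")
  disease_names <- c(diseases$raw, "Stem rot")  # last one exercises local minting

  maybe <- function(p) stats::runif(1) < p
  mess_term <- function(canonical) {
    out <- canonical
    if (maybe(m$case)) out <- perturb_case(out)
    if (maybe(m$punct)) out <- perturb_punct(out)
    out
  }
  org_raw <- function(row) {
    nm <- if (nzchar(row$common_name) && maybe(m$common)) row$common_name
          else row$scientific_name
    if (maybe(m$case)) nm <- perturb_case(nm)
    nm
  }

  pathogens <- taxa[taxa$role == "pathogen", ]
  plant_hosts <- taxa[taxa$role == "plant_host", ]
  animal_hosts <- taxa[taxa$role == "animal_host", ]

  n_total <- spec$n_records + spec$n_animal_records
  records <- vector("list", n_total)
  manifest <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    animal <- i > spec$n_records
    pa <- pathogens[sample(nrow(pathogens), 1), ]
    ho <- if (animal) animal_hosts[sample(nrow(animal_hosts), 1), ]
          else plant_hosts[sample(nrow(plant_hosts), 1), ]
    phen <- terms$phenotype[sample(nrow(terms$phenotype), 1), ]
    ev <- terms$evidence[sample(nrow(terms$evidence), 1), ]
    gr <- terms$in_vitro_growth[sample(nrow(terms$in_vitro_growth), 1), ]
    gene <- sample(gene_pool, 1)
    dis <- sample(disease_names, 1)
    dbt <- dbtypes[sample(nrow(dbtypes), 1), ]
    accession <- sprintf("P%05d", sample.int(99999, 1))
    pmids <- as.character(sample.int(3e7, sample(1:2, 1)))
    gos <- sprintf("GO:%07d", sample.int(9999999, sample(0:2, 1)))

    args <- list(
      phibase_accession = sprintf("PHI:%d", 1000 + i),
      pathogen_species = org_raw(pa), experimental_host = org_raw(ho),
      phenotype_of_mutant = mess_term(phen$canonical_label),
      gene_name = gene,
      pathogen_taxid = pa$taxon_id, host_taxid = ho$taxon_id,
      go_annotations = gos, literature_ids = pmids
    )
    if (!maybe(m$missing)) { args$db_type <- dbt$raw; args$accession <- accession }
    if (!maybe(m$missing)) args$locus_id <- sprintf("LOC_%05d", sample.int(99999, 1))
    if (!maybe(m$missing)) args$experimental_evidence <- mess_term(ev$canonical_label)
    if (!maybe(m$missing)) args$in_vitro_growth <- mess_term(gr$canonical_label)
    if (!maybe(m$missing)) args$disease_name <- dis
    if (!maybe(m$missing)) args$strain <- sprintf("strain %d", sample.int(99, 1))
    if (!maybe(m$missing)) args$associated_strain <- sprintf("isolate %d", sample.int(99, 1))
    if (!maybe(m$missing))
      args$aa_sequence <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       30, replace = TRUE), collapse = "")
    if (!maybe(m$missing))
      args$nt_sequence <- paste(sample(c("A", "C", "G", "T"), 60,
                                       replace = TRUE), collapse = "")
    if (!maybe(m$missing))
      args$function_text <- sprintf("%s pathway signalling component", gene)
    records[[i]] <- do.call(interaction_record, args)

    manifest[[i]] <- data.frame(
      phibase_accession = args$phibase_accession,
      pathogen_name = pa$scientific_name, pathogen_taxid = pa$taxon_id,
      host_name = ho$scientific_name, host_taxid = ho$taxon_id,
      phenotype_label = phen$canonical_label, phenotype_uri = phen$uri,
      evidence_label = if (is.null(args$experimental_evidence)) NA
                       else ev$canonical_label,
      evidence_uri = if (is.null(args$experimental_evidence)) NA else ev$uri,
      growth_label = if (is.null(args$in_vitro_growth)) NA
                     else gr$canonical_label,
      growth_uri = if (is.null(args$in_vitro_growth)) NA else gr$uri,
      disease_name = if (is.null(args$disease_name)) NA else dis,
      disease_uri = if (is.null(args$disease_name)) NA
                    else disease_to_uri(dis, tables$disease, scheme),
      gene_name = gene, stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, manifest)
  xml <- write_phibase_xml(records)
  allowlist <- data.frame(taxon_id = plant_hosts$taxon_id,
                          name_pattern = plant_hosts$scientific_name,
                          stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(xml, file.path(dir, "records.xml"), sep = "", useBytes = TRUE)
    for (d in names(tables))
      utils::write.table(tables[[d]]$entries, file.path(dir, paste0(d, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(allowlist, file.path(dir, "allowlist.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(records = records, xml = xml, tables = tables,
                 manifest = manifest, allowlist = allowlist))
}

#' The canonical worked-example record
#'
#' A fixed record (accession `PHI:11`) with a rice host, a rice blast
#' pathogen, a UniProt cross-reference and an "Increased virulence"
#' phenotype -- the record the worked-example tests transform.  Synthetic:
#' organism names and well-known identifiers are real, everything else
#' is illustrative.
#'
#' @return A `phi_record`.
#' @export
reference_record <- function() {
  interaction_record(
    phibase_accession = "PHI:11",
    pathogen_species = "Magnaporthe oryzae", pathogen_taxid = 318829L,
    experimental_host = "Rice", host_taxid = 4530L,
    phenotype_of_mutant = "Increased virulence",
    experimental_evidence = "Gene disruption",
    in_vitro_growth = "No change",
    disease_name = "Rice blast",
    gene_name = "PMK1", locus_id = "MGG_09565",
    db_type = "UNIPROT", accession = "P22287",
    strain = "Guy11",
    function_text = "MAP kinase required for appressorium formation",
    aa_sequence = "MSRANPPQRR", nt_sequence = "ATGTCTCGTGCCAATCCT",
    go_annotations = c("GO:0004707"),
    literature_ids = c("1234567")
  )
}
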