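# Identity-mapping harmonization --------------------------------------------
#
# Descriptive free-text fields in the dump are inconsistent in
# capitalization and punctuation ("Reduced virulence," vs "reduced
# virulence").  Curated mapping tables assign every semantically
# identical raw string one globally unique controlled-vocabulary URI.
# Before lookup, raw keys pass through a minimal normalization rule that
# covers exactly the defect classes observed: case-fold, collapse
# internal whitespace, strip trailing punctuation.

#' Normalize a raw descriptive term for table lookup
#' @param x character vector.
#' @return Normalized keys: case-folded, whitespace-collapsed, trailing
#'   punctuation stripped.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  sub("[[:punct:][:space:]]+$", "", x)
}

slugify <- function(x) {
  x <- normalize_term(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

MAPPING_DOMAINS <- c("phenotype", "evidence", "in_vitro_growth",
                     "species", "dbtype", "disease")

mapping_columns <- function(domain) {
  switch(domain,
    species = c("raw", "scientific_name", "taxon_id", "rank", "common_name"),
    dbtype  = c("raw", "prefix", "edam_uri"),
    disease = c("raw", "uri"),
    c("raw", "canonical_label", "uri")
  )
}

target_column <- function(domain) {
  switch(domain, species = "taxon_id", dbtype = "prefix", "uri")
}

#' Construct a mapping table from a data frame
#'
#' @param df data frame with the domain's columns (see
#'   [load_mapping_table()] for the layouts).
#' @param domain one of `"phenotype"`, `"evidence"`, `"in_vitro_growth"`,
#'   `"species"`, `"dbtype"`, `"disease"`.
#' @return A `phi_mapping_table`: lookup is by normalized raw key and is
#'   deterministic — conflicting duplicate keys are rejected.
#' @export
mapping_table <- function(df, domain = MAPPING_DOMAINS) {
  domain <- match.arg(domain)
  need <- mapping_columns(domain)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    phi_stop("phi_bad_table",
             sprintf("%s table lacks column(s): %s", domain,
                     paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  uri_cols <- intersect(c("uri", "edam_uri", "prefix"), names(df))
  for (cc in uri_cols) {
    bad <- nzchar(df[[cc]]) & !grepl("^[a-z][a-z0-9+.-]*:", df[[cc]])
    if (any(bad))
      phi_stop("phi_bad_table",
               sprintf("%s table: malformed URI in column %s: %s",
                       domain, cc, df[[cc]][which(bad)[1]]))
  }
  key <- normalize_term(df$raw)
  tgt <- as.character(df[[target_column(domain)]])
  by_key <- split(tgt, key)
  conflict <- names(by_key)[vapply(by_key, function(v)
    length(unique(v)) > 1, TRUE)]
  if (length(conflict))
    phi_stop("phi_conflicting_mapping",
             sprintf("%s table: normalized key(s) map to multiple targets: %s",
                     domain, paste(conflict, collapse = "; ")))
  keep <- !duplicated(key)
  entries <- df[keep, , drop = FALSE]
  rownames(entries) <- key[keep]
  structure(list(domain = domain, entries = entries),
            class = "phi_mapping_table")
}

#' Load a curated mapping table from TSV
#'
#' All tables are UTF-8 TSV with a header row.  Columns by domain:
#' * `phenotype` / `evidence` / `in_vitro_growth`: `raw`,
#'   `canonical_label`, `uri`
#' * `species`: `raw`, `scientific_name`, `taxon_id`, `rank`
#'   (`species`/`genus`), `common_name` (may be empty)
#' * `dbtype`: `raw`, `prefix` (an Identifiers.org URI prefix),
#'   `edam_uri` (the EDAM identifier-kind concept)
#' * `disease`: `raw`, `uri` (a DBpedia article URI)
#'
#' @param path TSV file path.
#' @param domain mapping domain (see [mapping_table()]).
#' @return A `phi_mapping_table`.
#' @export
load_mapping_table <- function(path, domain = MAPPING_DOMAINS) {
  domain <- match.arg(domain)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(
      rep(list(character()), length(mapping_columns(domain))),
      mapping_columns(domain)), stringsAsFactors = FALSE)
  }
  mapping_table(df, domain)
}

#' @export
print.phi_mapping_table <- function(x, ...) {
  cat(sprintf("<phi_mapping_table '%s': %d entries>\n",
              x$domain, nrow(x$entries)))
  invisible(x)
}

table_lookup <- function(table, raw) {
  key <- normalize_term(raw)
  if (key %in% rownames(table$entries))
    table$entries[key, , drop = FALSE]
  else NULL
}

#' Collector for unmapped raw terms
#'
#' Accumulates the raw strings that missed their mapping table during a
#' transformation run, for the unmapped-terms report (TSV: raw, domain,
#' count).
#' @return A `phi_unmapped_report` environment.
#' @export
unmapped_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  structure(e, class = "phi_unmapped_report")
}

record_unmapped <- function(collector, raw, domain) {
  if (!is.null(collector))
    collector$rows[[length(collector$rows) + 1]] <- c(raw = raw,
                                                      domain = domain)
  invisible(NULL)
}

#' @rdname unmapped_collector
#' @param collector a `phi_unmapped_report`.
#' @return `unmapped_report()` returns a data frame `raw`, `domain`,
#'   `count`.
#' @export
unmapped_report <- function(collector) {
  if (length(collector$rows) == 0)
    return(data.frame(raw = character(), domain = character(),
                      count = integer(), stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, collector$rows),
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df[c("raw", "domain")], FUN = sum)
  agg[order(agg$domain, agg$raw), , drop = FALSE]
}

#' Harmonize a raw descriptive term to a controlled-vocabulary class
#'
#' @param raw non-empty raw string from the dump.
#' @param table the domain's [mapping_table()].
#' @param policy `"strict"` errors on a miss; `"mint"` coins a new term
#'   in the local ontology namespace (stable across runs: the fragment is
#'   the slugified normalized raw string) and logs it as unmapped.
#' @param scheme a [uri_scheme()] (supplies the minting namespace).
#' @param collector optional [unmapped_collector()].
#' @return A `phi_canonical_term`: `uri`, `label` (language-tagged) and
#'   optional `definition`.
#' @export
harmonize_term <- function(raw, table, policy = c("strict", "mint"),
                           scheme = uri_scheme(), collector = NULL) {
  policy <- match.arg(policy)
  if (!nzchar(trimws(raw)))
    phi_stop("phi_invalid_record", "cannot harmonize an empty term")
  row <- table_lookup(table, raw)
  if (!is.null(row)) {
    return(canonical_term(row$uri, row$canonical_label,
                          if ("definition" %in% names(row)) row$definition))
  }
  if (policy == "strict")
    phi_stop("phi_unmapped_term",
             sprintf("unmapped %s term: '%s'", table$domain, raw),
             raw = raw, domain = table$domain)
  record_unmapped(collector, raw, table$domain)
  canonical_term(paste0(scheme$ontology_ns, toupper(substr(table$domain, 1, 4)),
                        "_", slugify(raw)),
                 normalize_term(raw))
}

canonical_term <- function(uri, label, definition = NULL) {
  structure(list(uri = uri, label = lit(label, "en"),
                 definition = definition),
            class = "phi_canonical_term")
}

#' Resolve a raw organism name to a taxon
#'
#' Handles both binomial scientific names and common names ("Rice" ->
#' *Oryza sativa*); resolution may bottom out at genus rank.  Strain text
#' is deliberately not consulted: most strains carry no taxon ID.
#'
#' @param raw_name non-empty organism name from the dump.
#' @param table the `species` [mapping_table()].
#' @return A `phi_taxon`: `scientific_name`, `common_name` (or `NA`),
#'   `taxon_id`, `rank`, and the Identifiers.org taxonomy URI.
#' @export
map_species <- function(raw_name, table) {
  if (!nzchar(trimws(raw_name)))
    phi_stop("phi_invalid_record", "cannot map an empty species name")
  row <- table_lookup(table, raw_name)
  if (is.null(row))
    phi_stop("phi_unmapped_term",
             sprintf("unmapped species name: '%s'", raw_name),
             raw = raw_name, domain = "species")
  common <- row$common_name
  if (is.na(common) || !nzchar(common)) common <- NA_character_
  structure(list(
    scientific_name = row$scientific_name, common_name = common,
    taxon_id = as.integer(row$taxon_id), rank = row$rank,
    taxon_uri = paste0(NS$idorg_taxonomy, as.integer(row$taxon_id))
  ), class = "phi_taxon")
}

#' Build a typed Identifiers.org cross-reference
#'
#' Maps the dump's `DB_Type` tag to its Identifiers.org URI prefix and
#' EDAM identifier-kind concept, then appends the raw accession.
#'
#' @param db_type raw `DB_Type` string, e.g. `"ENTREZ PROTEIN"`.
#' @param accession non-empty raw accession.
#' @param prefix_table the `dbtype` [mapping_table()].
#' @return A `phi_xref`: `raw_dbtype`, `raw_accession`, `uri`,
#'   `edam_type`.
#' @export
xref_to_uri <- function(db_type, accession, prefix_table) {
  if (!nzchar(trimws(accession)))
    phi_stop("phi_invalid_record", "cannot cross-reference an empty accession")
  row <- table_lookup(prefix_table, db_type)
  if (is.null(row))
    phi_stop("phi_unmapped_term",
             sprintf("unknown DbType: '%s'", db_type),
             raw = db_type, domain = "dbtype")
  structure(list(raw_dbtype = db_type, raw_accession = accession,
                 uri = paste0(row$prefix, accession),
                 edam_type = row$edam_uri),
            class = "phi_xref")
}

#' Resolve a disease name to a URI
#'
#' Curated names resolve to their DBpedia article URI; unmapped names get
#' a deterministic locally minted URI in the ontology namespace (same
#' name, same URI on every run), so the operation always succeeds.
#'
#' @param name non-empty disease name.
#' @param table the `disease` [mapping_table()].
#' @param scheme a [uri_scheme()].
#' @return Absolute URI string.
#' @export
disease_to_uri <- function(name, table, scheme = uri_scheme()) {
  if (!nzchar(trimws(name)))
    phi_stop("phi_invalid_record", "cannot resolve an empty disease name")
  row <- table_lookup(table, name)
  if (!is.null(row)) return(row$uri)
  paste0(scheme$ontology_ns, "DISEASE_", slugify(name))
}
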