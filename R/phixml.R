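# Canonical XML dialect ------------------------------------------------------
#
# The source database's dump format has no formal schema, so this module
# fixes one: a <Records> root holding one <Record> element per
# interaction, with the twenty selected tags below as children.
# GO_annotation and Literature_ID may repeat and accumulate into lists in
# document order; unknown sibling tags are tolerated and ignored.

PHI_TAGS <- c(
  phibase_accession     = "PHI-base_accession",
  db_type               = "DB_Type",
  accession             = "Accession",
  associated_strain     = "Associated_strain",
  gene_name             = "Gene_name",
  locus_id              = "Locus_ID",
  pathogen_taxid        = "Pathogen_NCBI_Taxonomy_ID",
  pathogen_species      = "Pathogen_species",
  strain                = "Strain",
  disease_name          = "Disease_name",
  host_taxid            = "Host_NCBI_Taxonomy_ID",
  experimental_host     = "Experimental_host",
  function_text         = "Function",
  phenotype_of_mutant   = "Phenotype_of_mutant",
  experimental_evidence = "Experimental_evidence",
  in_vitro_growth       = "In_vitro_growth",
  aa_sequence           = "AA_sequence",
  nt_sequence           = "NT_sequence",
  go_annotations        = "GO_annotation",
  literature_ids        = "Literature_ID"
)
PHI_MULTI <- c("go_annotations", "literature_ids")
PHI_REQUIRED <- c("phibase_accession", "pathogen_species",
                  "experimental_host", "phenotype_of_mutant")

AA_ALPHABET <- "^[ACDEFGHIKLMNPQRSTVWYBJXZUO*]+$"
NT_ALPHABET <- "^[ACGTURYSWKMBDHVN]+$"

#' Construct a single pathogen-host interaction record
#'
#' The unit of transformation: one entry of the interaction database dump,
#' restricted to the twenty selected fields.  Scalar fields absent from
#' the dump are `NULL`; `go_annotations` and `literature_ids` are
#' (possibly empty) character vectors.
#'
#' @param phibase_accession record accession, e.g. `"PHI:11"` (required).
#' @param pathogen_species,experimental_host organism names, possibly
#'   common names (required).
#' @param phenotype_of_mutant raw phenotype text (required).
#' @param db_type,accession,associated_strain,gene_name,locus_id,strain,disease_name,function_text,experimental_evidence,in_vitro_growth,aa_sequence,nt_sequence
#'   optional scalar fields.
#' @param pathogen_taxid,host_taxid optional positive integer taxon IDs.
#' @param go_annotations,literature_ids character vectors (GO IDs,
#'   PubMed IDs).
#' @return A `phi_record` object.
#' @export
interaction_record <- function(phibase_accession, pathogen_species,
                               experimental_host, phenotype_of_mutant,
                               db_type = NULL, accession = NULL,
                               associated_strain = NULL, gene_name = NULL,
                               locus_id = NULL, pathogen_taxid = NULL,
                               strain = NULL, disease_name = NULL,
                               host_taxid = NULL, function_text = NULL,
                               experimental_evidence = NULL,
                               in_vitro_growth = NULL, aa_sequence = NULL,
                               nt_sequence = NULL,
                               go_annotations = character(),
                               literature_ids = character()) {
  if (!is.null(pathogen_taxid))
    pathogen_taxid <- suppressWarnings(as.integer(pathogen_taxid))
  if (!is.null(host_taxid))
    host_taxid <- suppressWarnings(as.integer(host_taxid))
  rec <- list(
    phibase_accession = phibase_accession, db_type = db_type,
    accession = accession, associated_strain = associated_strain,
    gene_name = gene_name, locus_id = locus_id,
    pathogen_taxid = pathogen_taxid, pathogen_species = pathogen_species,
    strain = strain, disease_name = disease_name, host_taxid = host_taxid,
    experimental_host = experimental_host, function_text = function_text,
    phenotype_of_mutant = phenotype_of_mutant,
    experimental_evidence = experimental_evidence,
    in_vitro_growth = in_vitro_growth, aa_sequence = aa_sequence,
    nt_sequence = nt_sequence,
    go_annotations = as.character(go_annotations),
    literature_ids = as.character(literature_ids)
  )
  validate_record(rec)
  structure(rec, class = "phi_record")
}

validate_record <- function(rec) {
  for (f in PHI_REQUIRED)
    if (is.null(rec[[f]]) || !nzchar(trimws(rec[[f]])))
      phi_stop("phi_invalid_record",
               sprintf("field '%s' is required and must be non-empty", f))
  for (f in c("pathogen_taxid", "host_taxid")) {
    v <- rec[[f]]
    if (!is.null(v)) {
      vi <- suppressWarnings(as.integer(v))
      if (is.na(vi) || vi < 1)
        phi_stop("phi_invalid_record",
                 sprintf("%s: '%s' is not a positive integer (%s)",
                         f, v, rec$phibase_accession))
    }
  }
  if (!is.null(rec$aa_sequence) &&
      !grepl(AA_ALPHABET, clean_seq(rec$aa_sequence)))
    phi_stop("phi_invalid_record",
             sprintf("aa_sequence of %s contains non-amino-acid characters",
                     rec$phibase_accession))
  if (!is.null(rec$nt_sequence) &&
      !grepl(NT_ALPHABET, clean_seq(rec$nt_sequence)))
    phi_stop("phi_invalid_record",
             sprintf("nt_sequence of %s contains non-nucleotide characters",
                     rec$phibase_accession))
  invisible(rec)
}

clean_seq <- function(x) toupper(gsub("\\s+", "", x))

#' @export
print.phi_record <- function(x, ...) {
  cat(sprintf("<phi_record %s: %s / %s, phenotype '%s'>\n",
              x$phibase_accession, x$pathogen_species, x$experimental_host,
              x$phenotype_of_mutant))
  invisible(x)
}

#' Parse an interaction-database XML dump
#'
#' Reads the canonical dialect (see package README): `<Record>` elements
#' under a single root, each carrying the twenty selected tags; unknown
#' sibling tags are ignored; repeated `GO_annotation` / `Literature_ID`
#' tags accumulate in document order; surrounding whitespace is stripped.
#'
#' @param input a file path, URL-free XML string, or raw vector.
#' @return List of [interaction_record()]s, in document order.
#' @seealso [write_phibase_xml()], [filter_records()]
#' @export
parse_phibase_xml <- function(input) {
  doc <- tryCatch(xml2::read_xml(input),
                  error = function(e)
                    phi_stop("phi_parse_error",
                             paste("malformed XML:", conditionMessage(e))))
  nodes <- xml2::xml_find_all(doc, "//Record")
  records <- lapply(nodes, function(node) {
    args <- list()
    for (f in names(PHI_TAGS)) {
      els <- xml2::xml_find_all(node, paste0("./", PHI_TAGS[[f]]))
      if (f %in% PHI_MULTI) {
        args[[f]] <- trimws(xml2::xml_text(els))
      } else if (length(els) > 0) {
        args[[f]] <- trimws(xml2::xml_text(els[[1]]))
      }
    }
    do.call(interaction_record, args)
  })
  acc <- vapply(records, `[[`, "", "phibase_accession")
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    phi_stop("phi_duplicate_accession",
             paste("duplicate accessions:", paste(dup, collapse = ", ")),
             duplicates = dup)
  records
}

#' Write interaction records as canonical XML
#'
#' Inverse of [parse_phibase_xml()]: emits one `<Record>` per record with
#' the canonical tag names in canonical order, omitting absent fields.
#' Output is deterministic, so `write(parse(x))` is idempotent.
#'
#' @param records list of `phi_record` objects.
#' @param path optional file path; when given the document is also
#'   written there (UTF-8).
#' @return The XML document as a character scalar, invisibly when `path`
#'   is given.
#' @export
write_phibase_xml <- function(records, path = NULL) {
  for (r in records) validate_record(r)
  body <- vapply(records, function(r) {
    fields <- character()
    for (f in names(PHI_TAGS)) {
      vals <- r[[f]]
      if (is.null(vals)) next
      for (v in vals)
        fields <- c(fields, paste0("    <", PHI_TAGS[[f]], ">", esc_xml(v),
                                   "</", PHI_TAGS[[f]], ">"))
    }
    paste(c("  <Record>", fields, "  </Record>"), collapse = "\n")
  }, "")
  out <- paste(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<Records>",
                 body, "</Records>", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "", useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Restrict records to an allowlisted set of hosts
#'
#' The original resource restricted itself to plant hosts by manual
#' curation; here the same restriction is configuration.  A record is
#' kept when its host taxon ID is in the allowlist, or its
#' `experimental_host` matches one of the allowlist name patterns
#' (case-insensitive regular expressions).
#'
#' @param records list of `phi_record`s.
#' @param taxon_ids integer vector of allowed host taxon IDs.
#' @param name_patterns character vector of host-name patterns.
#' @return The kept records, original order preserved, with an
#'   `"excluded"` attribute: a data frame reporting each excluded
#'   record's accession and host.
#' @export
filter_records <- function(records, taxon_ids = integer(),
                           name_patterns = character()) {
  if (length(taxon_ids) == 0 && length(name_patterns) == 0)
    phi_stop("phi_empty_allowlist", "the host allowlist must be non-empty")
  keep <- vapply(records, function(r) {
    (!is.null(r$host_taxid) &&
       as.integer(r$host_taxid) %in% as.integer(taxon_ids)) ||
      any(vapply(name_patterns,
                 function(p) grepl(p, r$experimental_host, ignore.case = TRUE),
                 TRUE))
  }, TRUE)
  excluded <- data.frame(
    phibase_accession = vapply(records[!keep], `[[`, "", "phibase_accession"),
    experimental_host = vapply(records[!keep], `[[`, "", "experimental_host"),
    stringsAsFactors = FALSE
  )
  structure(records[keep], excluded = excluded)
}

#' Read a host allowlist table
#'
#' TSV with header and columns `taxon_id` (integer, may be empty) and
#' `name_pattern` (may be empty); each non-empty cell contributes one
#' allowlist entry.
#'
#' @param path TSV file path.
#' @return `list(taxon_ids=, name_patterns=)` for [filter_records()].
#' @export
read_allowlist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  tid <- suppressWarnings(as.integer(df$taxon_id))
  list(taxon_ids = tid[!is.na(tid)],
       name_patterns = df$name_pattern[!is.na(df$name_pattern) &
                                         nzchar(df$name_pattern)])
}
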