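# Classed conditions -------------------------------------------------------

phi_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "phi_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' URI minting scheme for locally coined identifiers
#'
#' Minted URIs follow `authority/project/resolver/type/PREFIX_NNNNN`:
#' the resolver segment names the software that dereferences the URI, the
#' type segment partitions the identifier space, and the local part is an
#' opaque prefix plus zero-padded serial.  No key/value query parameters
#' are ever used, so identifiers stay stable as resolver software changes.
#'
#' @param authority URI prefix owning the namespace.
#' @param project path segment partitioning this project.
#' @param resolver path segment naming the resolver.
#' @param ontology_ns namespace for locally minted vocabulary terms.
#' @param type_registry named list: entity type -> `list(segment, prefix,
#'   pad)`; see [default_type_registry()].
#' @return A `phi_uri_scheme` object.
#' @examples
#' mint_uri("interaction", 4, uri_scheme())
#' @export
uri_scheme <- function(authority = "http://linkeddata.systems",
                       project = "SemanticPHIBase",
                       resolver = "Resource",
                       ontology_ns = "http://linkeddata.systems/ontologies/SemanticPHIBase#",
                       type_registry = default_type_registry()) {
  structure(list(authority = sub("/+$", "", authority), project = project,
                 resolver = resolver, ontology_ns = ontology_ns,
                 type_registry = type_registry),
            class = "phi_uri_scheme")
}

#' @rdname uri_scheme
#' @details The default registry covers every entity type the record
#'   builder mints.  Pad widths follow the printed exemplars: 5 digits for
#'   interaction/host tokens (`INT_00004`, `HOST_01757`), 6 for context
#'   tokens (`HOSTCON_000123`, `PATHCON_000001`).
#' @export
default_type_registry <- function() {
  reg <- list(
    interaction        = c("interaction", "INT", "5"),
    host               = c("host", "HOST", "5"),
    pathogen           = c("pathogen", "PATH", "5"),
    interactioncontext = c("interactioncontext", "INTCON", "6"),
    hostcontext        = c("hostcontext", "HOSTCON", "6"),
    pathogencontext    = c("pathogencontext", "PATHCON", "6"),
    gene               = c("gene", "GENE", "5"),
    allele             = c("allele", "ALLELE", "6"),
    description        = c("description", "DESC", "6"),
    investigation      = c("investigation", "INV", "6"),
    citation           = c("citation", "CIT", "6"),
    identifier         = c("identifier", "IDENT", "6"),
    sequence           = c("sequence", "SEQ", "6"),
    disease            = c("disease", "DIS", "5"),
    quality            = c("quality", "QUAL", "6")
  )
  lapply(reg, function(r) list(segment = r[1], prefix = r[2],
                               pad = as.integer(r[3])))
}

#' Mint an opaque entity URI
#'
#' @param entity_type a key of the scheme's type registry,
#'   e.g. `"interaction"`.
#' @param serial positive integer; must fit in the registered pad width
#'   (no silent widening).
#' @param scheme a [uri_scheme()].
#' @return Absolute URI string.
#' @export
mint_uri <- function(entity_type, serial, scheme = uri_scheme()) {
  reg <- scheme$type_registry[[entity_type]]
  if (is.null(reg))
    phi_stop("phi_unknown_type",
             sprintf("entity type '%s' is not in the URI scheme registry", entity_type))
  serial <- as.integer(serial)
  if (is.na(serial) || serial < 1)
    phi_stop("phi_bad_serial", "serial must be a positive integer")
  if (serial > 10^reg$pad - 1)
    phi_stop("phi_serial_overflow",
             sprintf("serial %d exceeds pad width %d for type '%s'",
                     serial, reg$pad, entity_type))
  paste0(scheme$authority, "/", scheme$project, "/", scheme$resolver, "/",
         reg$segment, "/", reg$prefix, "_",
         formatC(serial, width = reg$pad, flag = "0"))
}

#' Extract the opaque ID token (e.g. "INT_00004") from a minted URI
#' @param uri a URI minted by [mint_uri()].
#' @return The `PREFIX_NNNNN` token.
#' @export
id_token <- function(uri) sub("^.*/", "", uri)

# regex matching the minted-URI grammar of a scheme
minted_uri_pattern <- function(scheme) {
  alts <- vapply(scheme$type_registry, function(r) {
    sprintf("%s/%s_[0-9]{%d}", r$segment, r$prefix, r$pad)
  }, "")
  paste0("^", gsub("([.?+])", "\\\\\\1",
                   paste0(scheme$authority, "/", scheme$project, "/",
                          scheme$resolver, "/")),
         "(", paste(alts, collapse = "|"), ")$")
}

#' Is a URI locally minted under a scheme?
#' @param uri character vector of URIs.
#' @param scheme a [uri_scheme()].
#' @return Logical vector.
#' @export
is_minted_uri <- function(uri, scheme = uri_scheme()) {
  grepl(minted_uri_pattern(scheme), uri)
}

#' Compose a human-readable entity label
#'
#' Labels follow `Component type` + em dash + `free text` + em dash +
#' `ID token`, with the middle segment dropped when no free text applies,
#' and are tagged `@en` when attached to the graph.
#'
#' @param component_type e.g. `"Host"`.
#' @param text free-text value from the source record, or `NA`/`NULL`.
#' @param id_token the node's minted ID token.
#' @return A [lit()] with language tag `"en"`.
#' @examples
#' make_label("Host", "Oryza sativa", "HOST_01757")
#' @export
make_label <- function(component_type, text, id_token) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    lit(paste(component_type, id_token, sep = "—"), "en")
  } else {
    lit(paste(component_type, text, id_token, sep = "—"), "en")
  }
}

# Serial counters -----------------------------------------------------------

#' Serial-number state for URI minting
#'
#' A mutable counter per entity type, shared across all records of one
#' transformation run so minted URIs are unique and deterministic
#' (records are processed in accession sort order).
#'
#' @return An environment-backed `phi_counters` object.
#' @export
serial_counters <- function() {
  e <- new.env(parent = emptyenv())
  structure(e, class = "phi_counters")
}

#' @rdname serial_counters
#' @param counters a `phi_counters` object.
#' @param entity_type registry key.
#' @return `next_serial()` returns the next unused positive integer.
#' @export
next_serial <- function(counters, entity_type) {
  cur <- if (is.null(counters[[entity_type]])) 0L else counters[[entity_type]]
  assign(entity_type, cur + 1L, envir = counters)
  cur + 1L
}
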