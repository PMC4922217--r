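#' An ordered-serializable set of RDF statements
#'
#' `triple_set()` is the universal output currency of the package: every
#' transformation, metadata and validation step produces or consumes one.
#' Statements are subject/predicate/object rows where the object is either
#' a URI or a literal with an optional language tag.  An optional named
#' graph URI (used as the provenance identifier of the whole dataset) is
#' carried as an attribute and surfaces in the N-Quads serialization.
#'
#' The container is deliberately a plain data frame: graphs built here are
#' ground (no blank nodes), so set operations and isomorphism reduce to
#' row operations.
#'
#' @param subject,predicate character vectors of absolute URIs.
#' @param object character vector: URIs or literal values per `is_literal`.
#' @param is_literal logical vector, `TRUE` where `object` is a literal.
#' @param lang character vector of language tags (`NA` for plain literals
#'   and URIs).
#' @param named_graph optional absolute URI naming the graph.
#' @return An object of class `phi_triples` (a data frame with columns
#'   `subject`, `predicate`, `object`, `is_literal`, `lang`).
#' @examples
#' ts <- triple_set(
#'   subject   = "http://example.org/a",
#'   predicate = "http://www.w3.org/2000/01/rdf-schema#label",
#'   object    = "thing A", is_literal = TRUE, lang = "en"
#' )
#' nrow(ts)
#' @export
triple_set <- function(subject = character(), predicate = character(),
                       object = character(), is_literal = logical(),
                       lang = NA_character_, named_graph = NULL) {
  n <- length(subject)
  stopifnot(length(predicate) == n, length(object) == n)
  if (length(is_literal) == 0 && n > 0) is_literal <- rep(FALSE, n)
  is_literal <- rep_len(as.logical(is_literal), n)
  lang <- rep_len(as.character(lang), n)
  df <- data.frame(
    subject = as.character(subject), predicate = as.character(predicate),
    object = as.character(object), is_literal = is_literal, lang = lang,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("phi_triples", "data.frame"),
            named_graph = named_graph)
}

#' Language-tagged or plain literal marker
#'
#' Wraps a character value so that [ts_add()] stores it as a literal
#' rather than a URI.
#'
#' @param value character value(s).
#' @param lang language tag or `NA` for a plain literal.
#' @return A `phi_literal` object.
#' @export
lit <- function(value, lang = NA_character_) {
  structure(as.character(value), lang = as.character(lang),
            class = "phi_literal")
}

is_lit <- function(x) inherits(x, "phi_literal")

#' Append statements to a triple set
#'
#' @param ts a [triple_set()].
#' @param subject,predicate absolute URIs (recycled to the object length).
#' @param object a character vector of URIs, or a [lit()] value.
#' @return The extended `phi_triples` object.
#' @export
ts_add <- function(ts, subject, predicate, object) {
  if (length(object) == 0) return(ts)
  if (is_lit(object)) {
    new <- triple_set(rep_len(subject, length(object)),
                      rep_len(predicate, length(object)),
                      unclass(object), TRUE,
                      rep_len(attr(object, "lang"), length(object)))
  } else {
    new <- triple_set(rep_len(subject, length(object)),
                      rep_len(predicate, length(object)),
                      object, FALSE, NA_character_)
  }
  ts_rbind(ts, new)
}

ts_rbind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, 1L) > 0 | vapply(parts, nrow, 1L) == 0]
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  ng <- NULL
  for (p in parts) if (!is.null(attr(p, "named_graph"))) ng <- attr(p, "named_graph")
  structure(out, class = c("phi_triples", "data.frame"), named_graph = ng)
}

#' Union of triple sets with duplicate statements removed
#'
#' @param ... `phi_triples` objects.
#' @param named_graph named graph URI for the result (default: the last
#'   non-`NULL` one among the inputs).
#' @return A deduplicated `phi_triples` object.
#' @export
ts_union <- function(..., named_graph = NULL) {
  out <- ts_rbind(...)
  if (!is.null(named_graph)) attr(out, "named_graph") <- named_graph
  ts_unique(out)
}

#' @rdname ts_union
#' @param ts a `phi_triples` object.
#' @export
ts_unique <- function(ts) {
  key <- ts_key(ts)
  keep <- !duplicated(key)
  structure(as.data.frame(ts)[keep, , drop = FALSE],
            class = c("phi_triples", "data.frame"),
            named_graph = attr(ts, "named_graph"))
}

ts_key <- function(ts) {
  paste(ts$subject, ts$predicate, ts$object, ts$is_literal,
        ifelse(is.na(ts$lang), "", ts$lang), sep = "\r")
}

# canonical row order for byte-stable serialization
ts_sort <- function(ts) {
  o <- order(ts$subject, ts$predicate, ts$is_literal, ts$object,
             method = "radix")
  structure(as.data.frame(ts)[o, , drop = FALSE],
            class = c("phi_triples", "data.frame"),
            named_graph = attr(ts, "named_graph"))
}

#' Test whether two ground graphs contain the same statements
#'
#' Graphs produced by this package contain no blank nodes, so RDF graph
#' isomorphism reduces to set equality of statements.  The named-graph
#' attribute is not compared.
#'
#' @param a,b `phi_triples` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ts_isomorphic <- function(a, b) {
  setequal(ts_key(ts_unique(a)), ts_key(ts_unique(b)))
}

#' Set the named graph of a triple set
#' @param ts a `phi_triples` object.
#' @param uri absolute URI or `NULL`.
#' @return `ts` with the named-graph attribute replaced.
#' @export
ts_set_graph <- function(ts, uri) {
  attr(ts, "named_graph") <- uri
  ts
}

#' @export
print.phi_triples <- function(x, ...) {
  cat(sprintf("<phi_triples: %d statements, %d subjects%s>\n",
              nrow(x), length(unique(x$subject)),
              if (is.null(attr(x, "named_graph"))) ""
              else paste0(", graph ", attr(x, "named_graph"))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# subject-position statements of one node
ts_about <- function(ts, uri) {
  structure(as.data.frame(ts)[ts$subject == uri, , drop = FALSE],
            class = c("phi_triples", "data.frame"),
            named_graph = attr(ts, "named_graph"))
}

# first English (or any) label of a node, NA if unlabeled
ts_label <- function(ts, uri) {
  i <- which(ts$subject == uri & ts$predicate == NS$rdfs_label & ts$is_literal)
  if (length(i) == 0) NA_character_ else ts$object[i[1]]
}
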