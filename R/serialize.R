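# RDF serialization and parsing ---------------------------------------------
#
# The package emits three standards-conformant concrete syntaxes.  Turtle
# output is restricted to the line-oriented subset with absolute IRIs
# (every line is also a valid N-Triples statement), which keeps the
# output diff-stable and the round-trip parser exact.  RDF/XML is built
# textually with deterministic namespace prefixes and parsed back with
# xml2.  N-Quads adds the named-graph URI as the fourth term.

esc_ttl <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unesc_ttl <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

fmt_term <- function(object, is_literal, lang) {
  ifelse(is_literal,
         paste0("\"", esc_ttl(object), "\"",
                ifelse(is.na(lang) | lang == "", "", paste0("@", lang))),
         paste0("<", object, ">"))
}

#' Serialize a triple set
#'
#' @param ts a [triple_set()].
#' @param format one of `"turtle"`, `"rdfxml"`, `"nquads"`.  N-Quads
#'   requires the named-graph attribute to be set.
#' @param stylesheet optional URL; when given (RDF/XML only) an
#'   `xml-stylesheet` processing instruction referencing it is emitted,
#'   reproducing the stylesheet-based human-readable rendering trick.
#' @return A single character scalar (UTF-8) holding the document.
#' @examples
#' g <- ts_add(triple_set(), "http://example.org/x",
#'             "http://www.w3.org/2000/01/rdf-schema#label", lit("x", "en"))
#' cat(serialize_graph(g, "turtle"))
#' @export
serialize_graph <- function(ts, format = c("turtle", "rdfxml", "nquads"),
                            stylesheet = NULL) {
  format <- match.arg(format)
  ts <- ts_sort(ts_unique(ts))
  switch(format,
    turtle = {
      if (nrow(ts) == 0) return("")
      paste0(paste0("<", ts$subject, "> <", ts$predicate, "> ",
                    fmt_term(ts$object, ts$is_literal, ts$lang), " .",
                    collapse = "\n"), "\n")
    },
    nquads = {
      g <- attr(ts, "named_graph")
      if (is.null(g))
        phi_stop("phi_no_graph", "N-Quads output requires a named graph")
      if (nrow(ts) == 0) return("")
      paste0(paste0("<", ts$subject, "> <", ts$predicate, "> ",
                    fmt_term(ts$object, ts$is_literal, ts$lang),
                    " <", g, "> .", collapse = "\n"), "\n")
    },
    rdfxml = serialize_rdfxml(ts, stylesheet)
  )
}

split_uri <- function(uri) {
  # namespace/localname split at the last # or / followed by an XML name
  m <- regexpr("[A-Za-z_][A-Za-z0-9_.-]*$", uri)
  if (m == -1 || m == 1) phi_stop("phi_bad_uri",
                                  sprintf("cannot derive a QName from <%s>", uri))
  c(ns = substr(uri, 1, m - 1), local = substr(uri, m, nchar(uri)))
}

esc_xml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

serialize_rdfxml <- function(ts, stylesheet = NULL) {
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  parts <- t(vapply(ts$predicate, split_uri, c(ns = "", local = "")))
  nss <- sort(unique(c(rdf_ns, parts[, "ns"])))
  pfx <- setNames(paste0("ns", seq_along(nss)), nss)
  pfx[rdf_ns] <- "rdf"
  decls <- paste0(" xmlns:", pfx, "=\"", esc_xml(names(pfx)), "\"",
                  collapse = "")
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           if (!is.null(stylesheet))
             paste0("<?xml-stylesheet type=\"text/xsl\" href=\"",
                    esc_xml(stylesheet), "\"?>"),
           paste0("<rdf:RDF", decls, ">"))
  for (s in unique(ts$subject)) {
    rows <- ts[ts$subject == s, , drop = FALSE]
    out <- c(out, paste0("  <rdf:Description rdf:about=\"", esc_xml(s), "\">"))
    for (i in seq_len(nrow(rows))) {
      sp <- split_uri(rows$predicate[i])
      qn <- paste0(pfx[[sp["ns"]]], ":", sp["local"])
      if (rows$is_literal[i]) {
        langattr <- if (!is.na(rows$lang[i]) && nzchar(rows$lang[i]))
          paste0(" xml:lang=\"", rows$lang[i], "\"") else ""
        out <- c(out, paste0("    <", qn, langattr, ">",
                             esc_xml(rows$object[i]), "</", qn, ">"))
      } else {
        out <- c(out, paste0("    <", qn, " rdf:resource=\"",
                             esc_xml(rows$object[i]), "\"/>"))
      }
    }
    out <- c(out, "  </rdf:Description>")
  }
  paste0(paste(c(out, "</rdf:RDF>"), collapse = "\n"), "\n")
}

#' Parse a serialized graph back into a triple set
#'
#' Accepts the three formats [serialize_graph()] emits.  The Turtle/
#' N-Quads parser covers the line-oriented absolute-IRI subset this
#' package writes (which is the full N-Triples/N-Quads grammar without
#' blank nodes or typed literals).
#'
#' @param text character scalar (or raw vector) holding the document.
#' @param format one of `"turtle"`, `"rdfxml"`, `"nquads"`.
#' @return A `phi_triples` object; for N-Quads the named-graph attribute
#'   is restored from the (single) graph term.
#' @export
parse_graph <- function(text, format = c("turtle", "rdfxml", "nquads")) {
  format <- match.arg(format)
  if (is.raw(text)) text <- rawToChar(text)
  if (format == "rdfxml") return(parse_rdfxml(text))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:@([A-Za-z-]+))?)",
                if (format == "nquads") "\\s+<([^>]*)>", "\\s*\\.\\s*$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, 1L) == 0)
  if (length(bad))
    phi_stop("phi_parse_error",
             sprintf("unparsable statement at line %d: %s", bad[1], lines[bad[1]]))
  subj <- vapply(m, `[`, "", 2); pred <- vapply(m, `[`, "", 3)
  ouri <- vapply(m, `[`, "", 4); olit <- vapply(m, `[`, "", 5)
  lang <- vapply(m, `[`, "", 6)
  is_literal <- !nzchar(ouri)
  object <- ifelse(is_literal, unesc_ttl(olit), ouri)
  graph <- NULL
  if (format == "nquads" && length(m)) {
    graphs <- unique(vapply(m, `[`, "", 7))
    if (length(graphs) != 1)
      phi_stop("phi_parse_error", "multiple named graphs in N-Quads input")
    graph <- graphs
  }
  triple_set(subj, pred, object, is_literal,
             ifelse(nzchar(lang), lang, NA_character_), named_graph = graph)
}

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  nsmap <- xml2::xml_ns(doc)
  descs <- xml2::xml_find_all(
    doc, "/*[local-name()='RDF']/*[local-name()='Description']")
  out <- list()
  for (d in descs) {
    s <- xml2::xml_attr(d, "about")
    for (el in xml2::xml_children(d)) {
      qn <- xml2::xml_name(el, ns = nsmap)
      bits <- strsplit(qn, ":", fixed = TRUE)[[1]]
      pred <- if (length(bits) == 2) paste0(nsmap[[bits[1]]], bits[2]) else bits
      res <- xml2::xml_attr(el, "resource")
      if (!is.na(res)) {
        out[[length(out) + 1]] <- list(s, pred, res, FALSE, NA_character_)
      } else {
        lang <- xml2::xml_attr(el, "lang")
        out[[length(out) + 1]] <- list(s, pred, xml2::xml_text(el), TRUE,
                                       if (is.na(lang)) NA_character_ else lang)
      }
    }
  }
  if (!length(out)) return(triple_set())
  triple_set(vapply(out, `[[`, "", 1), vapply(out, `[[`, "", 2),
             vapply(out, `[[`, "", 3), vapply(out, function(x) x[[4]], TRUE),
             vapply(out, `[[`, "", 5))
}
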