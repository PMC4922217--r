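# Dual human/machine URI resolver -------------------------------------------
#
# Every minted URI dereferences through one code path: the entity's
# subject-position subgraph is extracted once (the DESCRIBE contract),
# then rendered either as RDF (machines) or as generic property-list
# HTML (humans) from that identical statement set.  Media selection is
# HTTP content negotiation; the browser-first default for unrecognized
# Accept values is HTML.

#' Extract the DESCRIBE subgraph of a URI
#'
#' Returns all statements with `uri` in subject position -- the scope the
#' generic HTML rendering displays.  Inbound (object-position)
#' statements are available behind a flag.
#'
#' @param uri the URI of interest.
#' @param store a `phi_triples` store.
#' @param include_inbound also include statements with `uri` as object.
#' @return A `phi_subgraph`: `list(focus=, statements=)`.  Raises a
#'   `phi_not_found` condition when the URI does not occur in the store.
#' @export
describe_entity <- function(uri, store, include_inbound = FALSE) {
  out <- ts_about(store, uri)
  if (include_inbound) {
    inb <- as.data.frame(store)[!store$is_literal & store$object == uri, ,
                                drop = FALSE]
    out <- ts_rbind(out, structure(inb,
                                   class = c("phi_triples", "data.frame")))
  }
  if (nrow(out) == 0)
    phi_stop("phi_not_found", sprintf("URI not in store: <%s>", uri))
  structure(list(focus = uri, statements = ts_unique(out)),
            class = "phi_subgraph")
}

esc_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a DESCRIBE subgraph as generic HTML
#'
#' The HTML equivalent of the machine view: document title and heading
#' from the focus label, then one section per statement -- predicate
#' name as a heading, the object as a hyperlink when it is a URI and as
#' plain text otherwise.  No statement is dropped.
#'
#' @param subgraph a `phi_subgraph` from [describe_entity()].
#' @return A single character scalar holding the HTML document.
#' @export
render_html <- function(subgraph) {
  st <- subgraph$statements
  label <- ts_label(st, subgraph$focus)
  if (is.na(label)) label <- subgraph$focus
  sections <- vapply(seq_len(nrow(st)), function(i) {
    pname <- tryCatch(split_uri(st$predicate[i])[["local"]],
                      error = function(e) st$predicate[i])
    val <- if (st$is_literal[i]) {
      esc_html(st$object[i])
    } else {
      sprintf("<a href=\"%s\">%s</a>", esc_html(st$object[i]),
              esc_html(st$object[i]))
    }
    sprintf("<h3>%s:</h3>\n<p style=\"text-indent: 50px\">%s</p>",
            esc_html(pname), val)
  }, "")
  paste0("<!DOCTYPE html>\n<html>\n<head><title>", esc_html(label),
         "</title></head>\n<body>\n<h1>About: ", esc_html(label),
         "</h1>\n", paste(sections, collapse = "\n"), "\n</body></html>\n")
}

#' Bundle a transformed dataset into a resolvable service
#'
#' @param transform a `phi_transform` from [transform_records()] (or any
#'   `phi_triples` store plus an `interactions` data frame).
#' @param config an [accessor_config()].
#' @param scheme a [uri_scheme()].
#' @param stylesheet_compat when `TRUE`, RDF/XML responses carry an
#'   `xml-stylesheet` processing instruction (the historical rendering
#'   trick) referencing `<authority>/styles/phi.xsl`.
#' @return A `phi_service` object for [resolve_request()].
#' @export
phi_service <- function(transform, config = accessor_config(),
                        scheme = uri_scheme(), stylesheet_compat = FALSE) {
  structure(list(store = transform$graph,
                 interactions = transform$interactions,
                 config = config, scheme = scheme,
                 stylesheet = if (stylesheet_compat)
                   paste0(scheme$authority, "/styles/phi.xsl") else NULL),
            class = "phi_service")
}

pick_media <- function(accept) {
  # first supported type wins; browser-first default otherwise
  types <- trimws(vapply(strsplit(unlist(strsplit(accept, ",")), ";"),
                         `[`, "", 1))
  for (t in types) {
    if (t %in% c("application/rdf+xml", "application/xml")) return("rdfxml")
    if (t %in% c("text/turtle", "application/n-triples")) return("turtle")
    if (t %in% c("text/html", "application/xhtml+xml", "*/*")) return("html")
  }
  if (length(types) == 0 || all(!nzchar(types))) return("html")
  NA_character_
}

response <- function(status, content_type, body)
  structure(list(status = status, content_type = content_type, body = body),
            class = "phi_response")

serve_graph <- function(graph, focus, media, stylesheet = NULL) {
  if (media == "html") {
    sub <- describe_entity(focus, graph)
    return(response(200L, "text/html", render_html(sub)))
  }
  sub <- describe_entity(focus, graph)
  if (media == "rdfxml")
    response(200L, "application/rdf+xml",
             serialize_graph(sub$statements, "rdfxml",
                             stylesheet = stylesheet))
  else
    response(200L, "text/turtle", serialize_graph(sub$statements, "turtle"))
}

url_path <- function(x) sub("^[a-z][a-z0-9+.-]*://[^/]+", "", x)

#' Resolve a request path for humans or machines
#'
#' Routes: `/<project>/<resolver>/<type>/<ID>` dereferences a minted
#' entity; `/<project>/Metadata` and `/<project>/Metadata/<token>` serve
#' the accessor layers; the concept-scheme document resolves at its own
#' path.  Unknown URIs give 404; an Accept header offering none of
#' HTML/Turtle/RDF-XML gives 406.
#'
#' @param service a [phi_service()].
#' @param path URL path (a full URL is also accepted).
#' @param accept HTTP Accept header value.
#' @return A `phi_response`: `list(status=, content_type=, body=)`.
#' @export
resolve_request <- function(service, path, accept = "text/html") {
  media <- pick_media(accept)
  if (is.na(media))
    return(response(406L, "text/plain", "No acceptable representation\n"))
  path <- url_path(path)
  path <- sub("\\?.*$", "", path)
  cfg <- service$config
  scheme <- service$scheme

  meta_base <- url_path(cfg$base_url)
  theme_path <- url_path(cfg$theme)
  resource_base <- paste0("/", scheme$project, "/", scheme$resolver, "/")

  if (path == meta_base) {
    g <- repository_metadata(cfg, service$interactions$token)
    return(serve_graph(g, cfg$base_url, media, service$stylesheet))
  }
  if (path == theme_path) {
    g <- concept_scheme(cfg)
    return(serve_graph(g, cfg$theme, media, service$stylesheet))
  }
  if (startsWith(path, paste0(meta_base, "/"))) {
    token <- sub(paste0("^", meta_base, "/"), "", path)
    hit <- service$interactions$token == token
    if (!any(hit))
      return(response(404L, "text/plain", "Unknown meta-record\n"))
    g <- record_metadata(token, service$interactions$accession[hit][1],
                         cfg, scheme)
    return(serve_graph(g, meta_record_uri(cfg, token), media,
                       service$stylesheet))
  }
  if (startsWith(path, resource_base)) {
    uri <- paste0(scheme$authority, path)
    res <- tryCatch(serve_graph(service$store, uri, media,
                                service$stylesheet),
                    phi_not_found = function(e)
                      response(404L, "text/plain", "Unknown URI\n"))
    return(res)
  }
  response(404L, "text/plain", "Unknown path\n")
}

#' Write the whole published resource as static files
#'
#' Serverless publication: the dataset (N-Quads, named by the accessor
#' URL), repository metadata, concept scheme, every meta-record, and an
#' HTML + Turtle rendering of every minted entity.
#'
#' @param service a [phi_service()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
accessor_static <- function(service, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(name, content) {
    p <- file.path(out_dir, name)
    writeLines(content, p, sep = "", useBytes = TRUE)
    written <<- c(written, p)
  }
  store <- ts_set_graph(service$store, service$config$base_url)
  put("data.nq", serialize_graph(store, "nquads"))
  put("Metadata.ttl",
      serialize_graph(repository_metadata(service$config,
                                          service$interactions$token),
                      "turtle"))
  put("concept_scheme.ttl", serialize_graph(concept_scheme(service$config),
                                            "turtle"))
  for (i in seq_len(nrow(service$interactions))) {
    tok <- service$interactions$token[i]
    put(paste0("Metadata_", tok, ".ttl"),
        serialize_graph(record_metadata(tok,
                                        service$interactions$accession[i],
                                        service$config, service$scheme),
                        "turtle"))
  }
  minted <- unique(service$store$subject[
    is_minted_uri(service$store$subject, service$scheme)])
  for (u in minted) {
    sub <- describe_entity(u, service$store)
    put(paste0(id_token(u), ".html"), render_html(sub))
    put(paste0(id_token(u), ".ttl"),
        serialize_graph(sub$statements, "turtle"))
  }
  invisible(written)
}
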