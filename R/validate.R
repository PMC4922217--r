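# Model-shape validation -----------------------------------------------------

LITERAL_OK_PREDICATES <- function(vocab) c(vocab$has_value, NS$rdfs_label,
                                           NS$rdfs_comment)
METADATA_NS <- function() c(NS$dc11, NS$dcat, NS$pav, NS$daml, NS$foaf,
                            NS$skos, NS$schema, NS$void)

#' Validate a graph against the model-shape rules
#'
#' Violations are data, not exceptions.  Checked rules:
#' * `label`: every locally minted subject carries exactly one
#'   `rdfs:label`, and it has a language tag;
#' * `type`: every locally minted subject has at least one `rdf:type`;
#' * `has_value`: domain-data literals appear only behind the single
#'   `has_value` predicate (labels/comments and metadata-vocabulary
#'   annotations are exempt);
#' * `participants`: every Interaction has exactly two participants;
#' * `contexts`: every Interaction is manifested as at least two
#'   Interaction Contexts;
#' * `identifier_typed`: every `has_unique_identifier` object carries an
#'   EDAM identifier-kind type;
#' * `uri_grammar`: every URI under the resolver path with a type segment
#'   matches the minted-URI grammar (prefix + zero-padded serial).
#'
#' @param graph a `phi_triples`.
#' @param vocab a [model_vocabulary()].
#' @param scheme a [uri_scheme()].
#' @return A `phi_validation` data frame (`rule`, `node`, `message`);
#'   zero rows means the graph conforms.  A `notes` attribute lists
#'   convention-based placements (function text and in vitro growth
#'   nodes, whose position in the model is a package convention).
#' @export
validate_graph <- function(graph, vocab = model_vocabulary(),
                           scheme = uri_scheme()) {
  v <- list()
  bad <- function(rule, node, message)
    v[[length(v) + 1]] <<- data.frame(rule = rule, node = node,
                                      message = message,
                                      stringsAsFactors = FALSE)
  df <- as.data.frame(graph)
  subjects <- unique(df$subject)
  minted <- subjects[is_minted_uri(subjects, scheme)]

  for (s in minted) {
    lab <- which(df$subject == s & df$predicate == NS$rdfs_label)
    if (length(lab) == 0) {
      bad("label", s, "minted node has no rdfs:label")
    } else if (length(lab) > 1) {
      bad("label", s, "minted node has multiple rdfs:label statements")
    } else if (is.na(df$lang[lab]) || !nzchar(df$lang[lab])) {
      bad("label", s, "rdfs:label lacks a language tag")
    }
    if (!any(df$subject == s & df$predicate == NS$rdf_type))
      bad("type", s, "minted node has no rdf:type")
  }

  ok_preds <- LITERAL_OK_PREDICATES(vocab)
  md_ns <- METADATA_NS()
  lit_rows <- which(df$is_literal)
  for (i in lit_rows) {
    p <- df$predicate[i]
    if (p %in% ok_preds) next
    if (any(startsWith(p, md_ns))) next
    bad("has_value", df$subject[i],
        sprintf("literal attached via <%s>; domain data may only use has_value", p))
  }

  ints <- df$subject[df$predicate == NS$rdf_type &
                       df$object == vocab$cls_interaction]
  for (s in unique(ints)) {
    np <- sum(df$subject == s & df$predicate == vocab$has_participant)
    if (np != 2)
      bad("participants", s,
          sprintf("interaction has %d participants; expected exactly 2", np))
    nc <- sum(df$subject == s & df$predicate == vocab$is_manifested_as)
    if (nc < 2)
      bad("contexts", s,
          sprintf("interaction has %d contexts; expected at least 2", nc))
  }

  idents <- unique(df$object[df$predicate == vocab$has_unique_identifier &
                               !df$is_literal])
  for (u in idents) {
    types <- df$object[df$subject == u & df$predicate == NS$rdf_type]
    if (!any(startsWith(types, NS$edam)))
      bad("identifier_typed", u,
          "has_unique_identifier object lacks an EDAM identifier-kind type")
  }

  res_ns <- paste0(scheme$authority, "/", scheme$project, "/",
                   scheme$resolver, "/")
  all_uris <- unique(c(df$subject, df$object[!df$is_literal]))
  under <- all_uris[startsWith(all_uris, res_ns)]
  typed_path <- under[grepl("/", substr(under, nchar(res_ns) + 1,
                                        nchar(under)), fixed = TRUE)]
  for (u in typed_path)
    if (!is_minted_uri(u, scheme))
      bad("uri_grammar", u, "URI does not match the minted-URI grammar")

  out <- if (length(v)) do.call(rbind, v)
         else data.frame(rule = character(), node = character(),
                         message = character(), stringsAsFactors = FALSE)
  notes <- df$subject[df$predicate == NS$rdf_type &
                        df$object %in% c(vocab$cls_function, vocab$cls_growth)]
  attr(out, "notes") <- data.frame(
    node = unique(notes),
    note = "placement of this quality node in the model is a package convention",
    stringsAsFactors = FALSE)
  class(out) <- c("phi_validation", "data.frame")
  out
}
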