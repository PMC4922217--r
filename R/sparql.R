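# Restricted SPARQL engine ---------------------------------------------------
#
# Executes the packaged exploration queries against an in-memory
# phi_triples store.  The supported subset is exactly what those queries
# need: basic graph patterns with `a` and prefixed/absolute terms,
# FILTER with !=, CONTAINS(), str() and the negated-equality idiom,
# GRAPH ?var { ... } over the store's named graph, SELECT [DISTINCT]
# with optional (str(?x) as ?alias) projections, and ORDER BY.
# Federated SERVICE clauses and everything else are out of scope.

sparql_tokenize <- function(text) {
  # normalize typographic quotes, strip comments
  text <- gsub("[“”]", "\"", text)
  text <- gsub("#[^\n\"]*", "", text)
  pat <- "\"[^\"]*\"|[{}().]|[^\\s{}().]+"
  m <- gregexpr(pat, text, perl = TRUE)
  regmatches(text, m)[[1]]
}

expand_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
  if (tok == "a") return(NS$rdf_type)
  if (startsWith(tok, "?") || startsWith(tok, "\"")) return(tok)
  colon <- regexpr(":", tok, fixed = TRUE)
  if (colon > 0) {
    pfx <- substr(tok, 1, colon - 1)
    if (!pfx %in% names(prefixes))
      phi_stop("phi_sparql", sprintf("undeclared prefix '%s:'", pfx))
    return(paste0(prefixes[[pfx]], substr(tok, colon + 1, nchar(tok))))
  }
  phi_stop("phi_sparql", sprintf("cannot interpret term '%s'", tok))
}

parse_where <- function(toks, prefixes) {
  patterns <- list(); filters <- list(); graph_var <- NULL
  i <- 1
  while (i <= length(toks)) {
    tok <- toks[i]
    if (tok == "." || tok == "{" || tok == "}") { i <- i + 1; next }
    if (toupper(tok) == "GRAPH") {
      graph_var <- toks[i + 1]
      i <- i + 2
      next  # inner braces handled by the skip above
    }
    if (toupper(tok) == "FILTER") {
      depth <- 0; j <- i + 1; expr <- character()
      repeat {
        t2 <- toks[j]
        if (t2 == "(") depth <- depth + 1
        if (t2 == ")") depth <- depth - 1
        expr <- c(expr, t2)
        j <- j + 1
        if (depth == 0) break
      }
      filters[[length(filters) + 1]] <- expr
      i <- j
      next
    }
    if (toupper(tok) %in% c("SELECT", "WHERE", "DISTINCT")) {
      # nested sub-select header tokens: the local queries never need
      # true sub-query semantics, their inner patterns are evaluated in
      # the same scope
      i <- i + 1
      next
    }
    if (i + 2 > length(toks))
      phi_stop("phi_sparql", sprintf("dangling pattern near '%s'", tok))
    patterns[[length(patterns) + 1]] <-
      vapply(toks[i:(i + 2)], expand_term, "", prefixes = prefixes)
    i <- i + 3
  }
  list(patterns = patterns, filters = filters, graph_var = graph_var)
}

match_pattern <- function(df, pat) {
  s <- pat[1]; p <- pat[2]; o <- pat[3]
  keep <- rep(TRUE, nrow(df))
  if (!startsWith(s, "?")) keep <- keep & df$subject == s
  if (!startsWith(p, "?")) keep <- keep & df$predicate == p
  if (startsWith(o, "\"")) {
    keep <- keep & df$is_literal & df$object == gsub("^\"|\"$", "", o)
  } else if (!startsWith(o, "?")) {
    keep <- keep & !df$is_literal & df$object == o
  }
  rows <- df[keep, , drop = FALSE]
  out <- list()
  if (startsWith(s, "?")) out[[substring(s, 2)]] <- rows$subject
  if (startsWith(p, "?")) out[[substring(p, 2)]] <- rows$predicate
  if (startsWith(o, "?")) out[[substring(o, 2)]] <- rows$object
  if (!length(out)) {
    # all-constant pattern: acts as an existence test
    tab <- as.data.frame(matrix(nrow = min(nrow(rows), 1L), ncol = 0))
    return(tab)
  }
  unique(as.data.frame(out, stringsAsFactors = FALSE))
}

apply_filter <- function(bind, expr) {
  txt <- paste(expr, collapse = " ")
  get_var <- function(v) bind[[v]]
  # CONTAINS(str(?x), "s") / CONTAINS(?x, "s")
  m <- regmatches(txt, regexec(
    "CONTAINS\\s*\\(\\s*(?:str\\s*\\(\\s*)?\\?(\\w+)\\s*\\)?\\s*,\\s*\"([^\"]*)\"",
    txt, ignore.case = TRUE))[[1]]
  if (length(m)) return(bind[grepl(m[3], get_var(m[2]), fixed = TRUE), ,
                              drop = FALSE])
  # ?a != ?b
  m <- regmatches(txt, regexec("\\?(\\w+)\\s*!=\\s*\\?(\\w+)", txt))[[1]]
  if (length(m)) return(bind[get_var(m[2]) != get_var(m[3]), , drop = FALSE])
  # !str(?x) = "s"   (negated string equality)
  m <- regmatches(txt, regexec(
    "!\\s*str\\s*\\(\\s*\\?(\\w+)\\s*\\)\\s*=\\s*\"([^\"]*)\"", txt))[[1]]
  if (length(m)) return(bind[get_var(m[2]) != m[3], , drop = FALSE])
  # str(?x) = "s" / ?x = "s"
  m <- regmatches(txt, regexec(
    "(?:str\\s*\\(\\s*)?\\?(\\w+)\\s*\\)?\\s*=\\s*\"([^\"]*)\"", txt))[[1]]
  if (length(m)) return(bind[get_var(m[2]) == m[3], , drop = FALSE])
  phi_stop("phi_sparql", sprintf("unsupported FILTER expression: %s", txt))
}

parse_projection <- function(sel_text) {
  toks <- strsplit(gsub("[()]", " ", sel_text), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & toupper(toks) != "DISTINCT"]
  items <- list(); i <- 1
  while (i <= length(toks)) {
    if (tolower(toks[i]) == "str") {
      v <- substring(toks[i + 1], 2); i <- i + 2
    } else if (startsWith(toks[i], "?")) {
      v <- substring(toks[i], 2); i <- i + 1
    } else {
      phi_stop("phi_sparql", sprintf("cannot parse projection near '%s'",
                                     toks[i]))
    }
    alias <- v
    if (i <= length(toks) && tolower(toks[i]) == "as") {
      alias <- substring(toks[i + 1], 2); i <- i + 2
    }
    items[[alias]] <- v
  }
  items
}

#' Execute a SPARQL SELECT query over an in-memory graph
#'
#' Supports the restricted subset used by the packaged queries (see the
#' source-level notes); anything outside it raises a `phi_sparql` error
#' rather than returning wrong answers.
#'
#' @param query SPARQL SELECT text.
#' @param graph a `phi_triples` store; its named-graph attribute is what
#'   `GRAPH ?var { ... }` binds.
#' @return A data frame with one column per projected variable/alias.
#' @examples
#' \dontrun{
#' sparql_select(packaged_query(1), tr$graph)
#' }
#' @export
sparql_select <- function(query, graph) {
  text <- gsub("[“”]", "\"", query)
  pm <- gregexpr("PREFIX\\s+(\\S+):\\s*<([^>]*)>", text, ignore.case = TRUE)
  pref <- regmatches(text, pm)[[1]]
  prefixes <- list(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  for (p in pref) {
    mm <- regexec("PREFIX\\s+(\\S+):\\s*<([^>]*)>", p, ignore.case = TRUE)
    g <- regmatches(p, mm)[[1]]
    prefixes[[g[2]]] <- g[3]
  }
  text <- gsub("PREFIX\\s+\\S+:\\s*<[^>]*>", "", text, ignore.case = TRUE)

  sel_m <- regexec("(?is)select\\s+(.*?)\\s*where", text, perl = TRUE)
  sel <- regmatches(text, sel_m)[[1]]
  if (!length(sel)) phi_stop("phi_sparql", "not a SELECT ... WHERE query")
  proj <- parse_projection(sel[2])
  distinct <- grepl("(?i)select\\s+distinct", text, perl = TRUE)

  order_m <- regmatches(text, regexec("(?i)ORDER\\s+BY\\s+\\?(\\w+)", text,
                                      perl = TRUE))[[1]]
  order_var <- if (length(order_m)) order_m[2] else NULL
  if (length(order_m)) text <- sub("(?i)ORDER\\s+BY\\s+\\?\\w+", "", text,
                                   perl = TRUE)

  body <- sub("(?s)^.*?\\{", "", text, perl = TRUE)
  body <- sub("\\}[^}]*$", "", body)
  w <- parse_where(sparql_tokenize(body), prefixes)

  df <- as.data.frame(graph)
  bind <- NULL
  for (pat in w$patterns) {
    tab <- match_pattern(df, pat)
    if (ncol(tab) == 0) {
      if (nrow(tab) == 0 && !is.null(bind)) bind <- bind[0, , drop = FALSE]
      if (nrow(tab) == 0 && is.null(bind)) bind <- data.frame()
      next
    }
    if (is.null(bind)) {
      bind <- tab
    } else {
      shared <- intersect(names(bind), names(tab))
      bind <- if (length(shared)) merge(bind, tab, by = shared)
              else merge(bind, tab, by = NULL)
    }
  }
  if (is.null(bind)) bind <- data.frame()
  if (!is.null(w$graph_var)) {
    gv <- substring(w$graph_var, 2)
    ng <- attr(graph, "named_graph")
    if (is.null(ng)) bind <- bind[0, , drop = FALSE]
    else bind[[gv]] <- if (nrow(bind)) ng else character()
  }
  for (f in w$filters) bind <- apply_filter(bind, f)

  if (!is.null(order_var) && order_var %in% names(bind))
    bind <- bind[order(bind[[order_var]], method = "radix"), , drop = FALSE]

  missing_vars <- setdiff(unlist(proj), names(bind))
  for (v in missing_vars) bind[[v]] <- rep(NA_character_, nrow(bind))
  out <- as.data.frame(setNames(lapply(proj, function(v) bind[[v]]),
                                names(proj)), stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (distinct) out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Load one of the packaged SPARQL queries
#'
#' Queries 1-3 and 7 run locally through [sparql_select()]; 4-6 federate
#' out to public endpoints (their files carry a `network-required`
#' marker) and are shipped as text only.
#'
#' @param n query number, 1 to 7.
#' @return The query text.
#' @export
packaged_query <- function(n) {
  path <- system.file("queries", sprintf("query%d.rq", n),
                      package = "phifair", mustWork = TRUE)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
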