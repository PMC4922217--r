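# Record-to-graph transformation --------------------------------------------
#
# One XML record becomes one Interaction rooted subgraph:
#
#   Interaction --has_participant--> Host / Pathogen participants,
#     each --is_member_of--> an Organism (the Identifiers.org taxon URI,
#     multi-typed with EFO/SIO role terms and OBI/SIO organism);
#   Interaction --is_manifested_as--> two Interaction Contexts:
#     the implicit wild-type "base state" (Description has_value
#     "BASE STATE", wild-type-genotype Pathogen Context, disease link)
#     and the mutant state (harmonized phenotype Description,
#     Investigation/Citation with Identifiers.org PubMed URIs);
#   mutant Pathogen Context --has_quality--> Allele --variant_of-->
#     Gene --is_proper_part_of--> pathogen Organism, with typed
#     cross-reference and sequence nodes hanging off the Gene.
#
# All literals attach through the single has_value predicate; every
# minted node gets exactly one @en label and at least one rdf:type.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1]) ||
                               !nzchar(a[1])) b else a

#' Build the RDF subgraph for one interaction record
#'
#' @param record a [interaction_record()] that passed host filtering.
#' @param tables named list of [mapping_table()]s: `phenotype`,
#'   `evidence`, `in_vitro_growth`, `species`, `dbtype`, `disease`.
#' @param scheme a [uri_scheme()].
#' @param vocab a [model_vocabulary()].
#' @param counters shared [serial_counters()] providing fresh serials.
#' @param policy harmonization policy, `"strict"` or `"mint"`.
#' @param collector optional [unmapped_collector()] for the
#'   unmapped-terms report.
#' @return A `phi_triples` graph with attributes `interaction` (the
#'   minted ID token), `accession`, and `entity_keys` (node identity keys
#'   consumed by [merge_shared_nodes()]).
#' @export
build_record_graph <- function(record, tables, scheme = uri_scheme(),
                               vocab = model_vocabulary(scheme),
                               counters = serial_counters(),
                               policy = "strict", collector = NULL) {
  ts <- triple_set()
  mint <- function(type) mint_uri(type, next_serial(counters, type), scheme)
  keys <- list()

  node <- function(uri, types, label) {
    ts <<- ts_add(ts, uri, NS$rdf_type, types)
    ts <<- ts_add(ts, uri, NS$rdfs_label, label)
    uri
  }
  organism_node <- function(taxon, role_types) {
    label_text <- if (is.na(taxon$common_name)) taxon$scientific_name
                  else sprintf("%s (%s)", taxon$scientific_name,
                               taxon$common_name)
    node(taxon$taxon_uri,
         c(vocab$cls_organism, vocab$ext_organism, role_types),
         lit(label_text, "en"))
  }

  host_tax <- map_species(record$experimental_host, tables$species)
  path_tax <- map_species(record$pathogen_species, tables$species)

  int <- mint("interaction")
  node(int, vocab$cls_interaction,
       make_label("Interaction", record$phibase_accession, id_token(int)))

  host <- mint("host")
  node(host, vocab$cls_host,
       make_label("Host", host_tax$scientific_name, id_token(host)))
  path <- mint("pathogen")
  node(path, vocab$cls_pathogen,
       make_label("Pathogen", path_tax$scientific_name, id_token(path)))
  ts <- ts_add(ts, int, vocab$has_participant, c(host, path))
  ts <- ts_add(ts, host, vocab$participates_in, int)
  ts <- ts_add(ts, path, vocab$participates_in, int)

  host_org <- organism_node(host_tax, vocab$ext_host)
  path_org <- organism_node(path_tax, vocab$ext_pathogen)
  ts <- ts_add(ts, host, vocab$is_member_of, host_org)
  ts <- ts_add(ts, path, vocab$is_member_of, path_org)
  keys[[length(keys) + 1]] <- c(node = host_org, kind = "organism",
                                key = host_tax$taxon_uri)
  keys[[length(keys) + 1]] <- c(node = path_org, kind = "organism",
                                key = path_tax$taxon_uri)

  # contexts: implicit wild-type base state + the recorded mutant state
  icb <- mint("interactioncontext")
  node(icb, vocab$cls_interaction_context,
       make_label("Interaction Context", "BASE STATE", id_token(icb)))
  icm <- mint("interactioncontext")
  pheno <- harmonize_term(record$phenotype_of_mutant, tables$phenotype,
                          policy, scheme, collector)
  node(icm, vocab$cls_interaction_context,
       make_label("Interaction Context", unclass(pheno$label), id_token(icm)))
  ts <- ts_add(ts, int, vocab$is_manifested_as, c(icb, icm))

  hcb <- mint("hostcontext")
  node(hcb, vocab$cls_host_context,
       make_label("Host Context", host_tax$scientific_name, id_token(hcb)))
  hcm <- mint("hostcontext")
  node(hcm, vocab$cls_host_context,
       make_label("Host Context", host_tax$scientific_name, id_token(hcm)))
  pcb <- mint("pathogencontext")
  node(pcb, c(vocab$cls_pathogen_context, vocab$ext_wild_type_genotype),
       make_label("Pathogen Context", "wild type", id_token(pcb)))
  pcm <- mint("pathogencontext")
  node(pcm, vocab$cls_pathogen_context,
       make_label("Pathogen Context", record$strain %||% NA, id_token(pcm)))
  ts <- ts_add(ts, icb, vocab$depends_on, c(hcb, pcb))
  ts <- ts_add(ts, icm, vocab$depends_on, c(hcm, pcm))

  # base-state description, disease, associated (wild-type) strain
  db <- mint("description")
  node(db, vocab$cls_description,
       make_label("Description", "BASE STATE", id_token(db)))
  ts <- ts_add(ts, db, vocab$has_value, lit("BASE STATE"))
  ts <- ts_add(ts, icb, vocab$has_quality, db)

  if (!is.null(record$disease_name)) {
    dis <- disease_to_uri(record$disease_name, tables$disease, scheme)
    node(dis, vocab$cls_disease_name,
         lit(paste("Disease Name", record$disease_name, sep = "—"), "en"))
    ts <- ts_add(ts, dis, vocab$has_value, lit(record$disease_name))
    # the disease manifests in the wild-type host: attaching it to the
    # base-state Host Context keeps interaction-context qualities
    # exclusively phenotypic Descriptions, as the packaged phenotype
    # query assumes
    ts <- ts_add(ts, hcb, vocab$has_quality, dis)
  }
  if (!is.null(record$associated_strain)) {
    st <- mint("quality")
    node(st, vocab$cls_strain,
         make_label("Strain", record$associated_strain, id_token(st)))
    ts <- ts_add(ts, st, vocab$has_value, lit(record$associated_strain))
    ts <- ts_add(ts, pcb, vocab$has_quality, st)
  }

  # mutant-state phenotype description
  dm <- mint("description")
  node(dm, c(vocab$cls_description, pheno$uri),
       make_label("Description", unclass(pheno$label), id_token(dm)))
  ts <- ts_add(ts, dm, vocab$has_value, pheno$label)
  ts <- ts_add(ts, icm, vocab$has_quality, dm)

  # investigation (harmonized experimental evidence) and citations
  inv <- mint("investigation")
  inv_types <- vocab$cls_investigation
  inv_text <- NA_character_
  if (!is.null(record$experimental_evidence)) {
    ev <- harmonize_term(record$experimental_evidence, tables$evidence,
                         policy, scheme, collector)
    inv_types <- c(inv_types, ev$uri)
    inv_text <- unclass(ev$label)
  }
  node(inv, inv_types, make_label("Investigation", inv_text, id_token(inv)))
  ts <- ts_add(ts, icm, vocab$is_output_of, inv)

  if (length(record$literature_ids) > 0) {
    cit <- mint("citation")
    node(cit, c(vocab$cls_citation, vocab$ext_creative_work),
         make_label("Citation", record$literature_ids[1], id_token(cit)))
    ts <- ts_add(ts, inv, vocab$citation, cit)
    for (pm in record$literature_ids) {
      pmu <- paste0(NS$idorg_pubmed, pm)
      node(pmu, vocab$edam_pubmed_id,
           lit(paste("PubMed Identifier", pm, sep = "—"), "en"))
      ts <- ts_add(ts, cit, vocab$has_unique_identifier, pmu)
    }
  }

  # allele -> gene -> pathogen organism
  gene <- mint("gene")
  gene_text <- record$gene_name %||% record$locus_id %||% NA
  node(gene, c(vocab$cls_gene, vocab$ext_gene),
       make_label("Gene", gene_text, id_token(gene)))
  ts <- ts_add(ts, gene, vocab$is_proper_part_of, path_org)
  gene_key <- paste(path_tax$taxon_uri,
                    record$gene_name %||% record$locus_id %||%
                      record$accession %||% id_token(gene), sep = "|")
  keys[[length(keys) + 1]] <- c(node = gene, kind = "gene", key = gene_key)

  allele <- mint("allele")
  node(allele, vocab$cls_allele,
       make_label("Allele", gene_text, id_token(allele)))
  ts <- ts_add(ts, allele, vocab$variant_of, gene)
  ts <- ts_add(ts, pcm, vocab$has_quality, allele)

  ident <- function(value, edam_type, kind_label) {
    u <- mint("identifier")
    node(u, edam_type, make_label(kind_label, value, id_token(u)))
    ts <<- ts_add(ts, u, vocab$has_value, lit(value))
    ts <<- ts_add(ts, gene, vocab$has_unique_identifier, u)
  }
  if (!is.null(record$gene_name))
    ident(record$gene_name, vocab$edam_gene_name, "Gene Name")
  if (!is.null(record$locus_id))
    ident(record$locus_id, vocab$edam_locus_id, "Locus ID")

  if (!is.null(record$accession)) {
    xref <- tryCatch(
      xref_to_uri(record$db_type %||% "", record$accession, tables$dbtype),
      phi_unmapped_term = function(e) {
        # unknown DbType is non-fatal: drop the cross-reference, keep the
        # record, and log the miss
        record_unmapped(collector, e$raw, "dbtype")
        NULL
      })
    if (!is.null(xref)) {
      node(xref$uri, xref$edam_type,
           lit(paste(xref$raw_dbtype, xref$raw_accession, sep = "—"), "en"))
      ts <- ts_add(ts, gene, vocab$has_unique_identifier, xref$uri)
    }
  }
  for (go in record$go_annotations) {
    gu <- paste0(NS$idorg_go, go)
    node(gu, vocab$edam_go_id,
         lit(paste("GO Concept ID", go, sep = "—"), "en"))
    ts <- ts_add(ts, gene, vocab$has_unique_identifier, gu)
  }

  seq_quality <- function(value, edam_type, kind_label) {
    u <- mint("sequence")
    node(u, c(vocab$cls_sequence, edam_type),
         make_label(kind_label, NA, id_token(u)))
    ts <<- ts_add(ts, u, vocab$has_value, lit(clean_seq(value)))
    ts <<- ts_add(ts, gene, vocab$has_quality, u)
  }
  if (!is.null(record$aa_sequence))
    seq_quality(record$aa_sequence, vocab$edam_protein_seq,
                "Protein Sequence")
  if (!is.null(record$nt_sequence))
    seq_quality(record$nt_sequence, vocab$edam_nucleotide_seq,
                "Nucleotide Sequence")

  if (!is.null(record$function_text)) {
    fu <- mint("description")
    node(fu, vocab$cls_function, make_label("Function", NA, id_token(fu)))
    ts <- ts_add(ts, fu, vocab$has_value, lit(record$function_text))
    ts <- ts_add(ts, gene, vocab$has_quality, fu)
  }
  if (!is.null(record$strain)) {
    st <- mint("quality")
    node(st, vocab$cls_strain,
         make_label("Strain", record$strain, id_token(st)))
    ts <- ts_add(ts, st, vocab$has_value, lit(record$strain))
    ts <- ts_add(ts, pcm, vocab$has_quality, st)
  }
  if (!is.null(record$in_vitro_growth)) {
    gr <- harmonize_term(record$in_vitro_growth, tables$in_vitro_growth,
                         policy, scheme, collector)
    gu <- mint("quality")
    node(gu, c(vocab$cls_growth, gr$uri),
         make_label("In Vitro Growth", unclass(gr$label), id_token(gu)))
    ts <- ts_add(ts, gu, vocab$has_value, gr$label)
    ts <- ts_add(ts, pcm, vocab$has_quality, gu)
  }

  keys_df <- as.data.frame(do.call(rbind, keys), stringsAsFactors = FALSE)
  structure(ts_unique(ts), interaction = id_token(int),
            accession = record$phibase_accession, entity_keys = keys_df)
}

#' Merge nodes shared between record graphs
#'
#' Organisms are shared by taxon URI (which holds by construction, since
#' the organism node *is* the Identifiers.org taxon URI).  Gene nodes are
#' merged when two records study the same gene of the same pathogen
#' (identity key: pathogen taxon + gene name, falling back to locus ID or
#' accession), making the Gene node the point of convergence between
#' interaction contexts.  Alleles are never merged: absent evidence to
#' the contrary, every context's allele is distinct.
#'
#' @param graphs list of graphs from [build_record_graph()] built with a
#'   shared counter state.
#' @return A single deduplicated `phi_triples` union in which merged
#'   nodes keep exactly one label (the canonical node's).
#' @export
merge_shared_nodes <- function(graphs) {
  if (length(graphs) == 1) return(graphs[[1]])
  keys <- do.call(rbind, lapply(graphs, attr, "entity_keys"))
  rewrite <- character()
  if (!is.null(keys)) {
    genes <- keys[keys$kind == "gene", , drop = FALSE]
    for (k in unique(genes$key)) {
      nodes <- sort(unique(genes$node[genes$key == k]))
      if (length(nodes) > 1)
        rewrite[nodes[-1]] <- nodes[1]
    }
  }
  graphs <- lapply(graphs, function(g) {
    df <- as.data.frame(g)
    dropped <- names(rewrite)
    # non-canonical labels would pile up on the merged node; drop them
    df <- df[!(df$subject %in% dropped & df$predicate == NS$rdfs_label), ,
             drop = FALSE]
    hit_s <- df$subject %in% dropped
    df$subject[hit_s] <- rewrite[df$subject[hit_s]]
    hit_o <- !df$is_literal & df$object %in% dropped
    df$object[hit_o] <- rewrite[df$object[hit_o]]
    structure(df, class = c("phi_triples", "data.frame"))
  })
  do.call(ts_union, graphs)
}

#' Transform a set of records into one dataset graph
#'
#' The top-level pipeline entry point: records are processed in
#' accession sort order (so minted URIs are deterministic across runs),
#' each becomes a record graph, shared nodes are merged, and the result
#' is stamped with the named graph that ties the data to its repository
#' metadata.
#'
#' @inheritParams build_record_graph
#' @param records list of `phi_record`s (already host-filtered).
#' @param named_graph URI of the named graph; by convention the FAIR
#'   Accessor URL, so provenance queries over the graph name resolve to
#'   the repository metadata.
#' @return A `phi_transform` list: `graph` (the merged `phi_triples`),
#'   `interactions` (data frame: `accession`, `token`, `uri`), and
#'   `unmapped` (the unmapped-terms report).
#' @export
transform_records <- function(records, tables, scheme = uri_scheme(),
                              vocab = model_vocabulary(scheme),
                              policy = "strict", named_graph = NULL) {
  acc <- vapply(records, `[[`, "", "phibase_accession")
  records <- records[order(acc, method = "radix")]
  counters <- serial_counters()
  collector <- unmapped_collector()
  graphs <- lapply(records, build_record_graph, tables = tables,
                   scheme = scheme, vocab = vocab, counters = counters,
                   policy = policy, collector = collector)
  merged <- if (length(graphs)) merge_shared_nodes(graphs) else triple_set()
  merged <- ts_set_graph(merged, named_graph)
  interactions <- data.frame(
    accession = vapply(graphs, attr, "", "accession"),
    token = vapply(graphs, attr, "", "interaction"),
    stringsAsFactors = FALSE
  )
  interactions$uri <- paste0(scheme$authority, "/", scheme$project, "/",
                             scheme$resolver, "/interaction/",
                             interactions$token)
  structure(list(graph = merged, interactions = interactions,
                 unmapped = unmapped_report(collector)),
            class = "phi_transform")
}

#' Audit that every populated input field is reachable in the graph
#'
#' Conservation check: each populated field of each record must surface
#' in the transformed graph as a `has_value` literal, inside a typed
#' cross-reference URI, or as its harmonized controlled-vocabulary class.
#'
#' @param records the transformed `phi_record`s.
#' @param graph the merged `phi_triples`.
#' @param tables the mapping tables used for the transformation.
#' @param scheme,policy as passed to [transform_records()].
#' @return Data frame `accession`, `field`, `covered`; conservation holds
#'   when all `covered` are `TRUE`.
#' @export
field_coverage <- function(records, graph, tables, scheme = uri_scheme(),
                           policy = "strict") {
  literals <- graph$object[graph$is_literal]
  uris <- unique(c(graph$subject, graph$predicate,
                   graph$object[!graph$is_literal]))
  uri_blob <- paste(uris, collapse = "\n")
  has_lit <- function(v) any(literals == v)
  in_uri <- function(v) grepl(v, uri_blob, fixed = TRUE)
  harm_ok <- function(v, dom) {
    term <- harmonize_term(v, tables[[dom]], policy, scheme)
    term$uri %in% uris || has_lit(unclass(term$label))
  }
  rows <- list()
  for (r in records) {
    for (f in setdiff(names(PHI_TAGS), "phibase_accession")) {
      vals <- r[[f]]
      if (is.null(vals) || length(vals) == 0) next
      for (v in vals) {
        covered <- switch(f,
          phenotype_of_mutant   = harm_ok(v, "phenotype"),
          experimental_evidence = harm_ok(v, "evidence"),
          in_vitro_growth       = harm_ok(v, "in_vitro_growth"),
          pathogen_species      = map_species(v, tables$species)$taxon_uri %in% uris,
          experimental_host     = map_species(v, tables$species)$taxon_uri %in% uris,
          pathogen_taxid        = paste0(NS$idorg_taxonomy, as.integer(v)) %in% uris,
          host_taxid            = paste0(NS$idorg_taxonomy, as.integer(v)) %in% uris,
          aa_sequence           = has_lit(clean_seq(v)),
          nt_sequence           = has_lit(clean_seq(v)),
          accession             = in_uri(v),
          db_type               = is.null(r$accession) || in_uri(r$accession),
          go_annotations        = in_uri(v),
          literature_ids        = paste0(NS$idorg_pubmed, v) %in% uris,
          disease_name          = has_lit(v),
          has_lit(v)
        )
        rows[[length(rows) + 1]] <- data.frame(
          accession = r$phibase_accession, field = f, covered = covered,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
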