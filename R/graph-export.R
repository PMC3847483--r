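num_str <- function(x) vapply(x, function(v) format(v, digits = 15), character(1))

# Flatten a pathway (plus optional expression) into node/edge tables shared
# by the GraphML and JSON writers. Bipartite: metabolite and reaction nodes.
pathway_graph_tables <- function(pathway) {
  reactions <- pathway$template$reactions
  subs <- split_multi(reactions$substrates)
  prods <- split_multi(reactions$products)
  metabolites <- unique(unlist(c(subs, prods)))
  rec_ecs <- template_reaction_ecs(pathway$template)

  node_rows <- list()
  for (m in metabolites) {
    node_rows[[m]] <- data.frame(
      id = m, kind = "metabolite", label = m, ec = "", sub_pathway = "",
      gap = "", proteins = "", ms = "", cs = "", region = "",
      validated = "", expr_proteins = "", stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reactions))) {
    rid <- reactions$reaction_id[i]
    a <- pathway$assignments[[rid]]
    prot <- unique(a$query_id)
    per_prot <- a[!duplicated(a$query_id), , drop = FALSE]
    node_rows[[rid]] <- data.frame(
      id = rid, kind = "reaction", label = rid,
      ec = paste(rec_ecs[[rid]], collapse = ";"),
      sub_pathway = reactions$sub_pathway[i],
      gap = if (rid %in% pathway$gaps) "true" else "false",
      proteins = paste(prot, collapse = ";"),
      ms = paste(num_str(per_prot$MS), collapse = ";"),
      cs = paste(num_str(per_prot$CS), collapse = ";"),
      region = paste(per_prot$region, collapse = ";"),
      validated = paste(tolower(per_prot$validated), collapse = ";"),
      expr_proteins = "", stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, node_rows)

  conds <- character(0)
  if (!is.null(pathway$expression)) {
    conds <- attr(pathway$overlay, "conditions")
    for (cn in conds) nodes[[paste0("expr_", cn)]] <- ""
    for (rid in names(pathway$expression)) {
      ex <- pathway$expression[[rid]]
      if (is.null(ex) || !nrow(ex)) next
      j <- match(rid, nodes$id)
      nodes$expr_proteins[j] <- paste(ex$protein_id, collapse = ";")
      for (cn in conds) {
        nodes[[paste0("expr_", cn)]][j] <- paste(num_str(ex[[cn]]),
                                                 collapse = ";")
      }
    }
  }

  edges <- do.call(rbind, lapply(seq_len(nrow(reactions)), function(i) {
    rid <- reactions$reaction_id[i]
    rbind(
      if (length(subs[[i]])) data.frame(source = subs[[i]], target = rid,
                                        role = "substrate",
                                        stringsAsFactors = FALSE),
      if (length(prods[[i]])) data.frame(source = rid, target = prods[[i]],
                                         role = "product",
                                         stringsAsFactors = FALSE))
  }))
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, conditions = conds)
}

#' Export a pathway as a GraphML or JSON graph
#'
#' Writes the reconstructed pathway as a directed bipartite graph of
#' metabolite and reaction nodes (substrate to reaction to product edges).
#' Reaction nodes carry their EC numbers, sub-pathway, gap flag, and the
#' `;`-joined lists of assigned protein ids with their MS/CS scores,
#' confidence regions and validation flags; when an expression overlay has
#' been attached ([attach_overlay()]), per-condition expression vectors of
#' the fold-change-passing proteins are added as further attributes. The
#' GraphML output parses with any generic GraphML reader (e.g. igraph);
#' JSON holds the same node/edge tables.
#'
#' @param pathway a [build_pathway()] result (optionally with an attached
#'   overlay).
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @param overlay optional [fold_change_filter()] result to attach before
#'   export.
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(pathway, path, format = c("graphml", "json"),
                                overlay = NULL) {
  stopifnot(inherits(pathway, "pathway"))
  if (!is.character(format) || !all(format %in% c("graphml", "json"))) {
    stop("unknown graph format; use 'graphml' or 'json'", call. = FALSE)
  }
  format <- match.arg(format)
  if (!is.null(overlay)) pathway <- attach_overlay(pathway, overlay)
  g <- pathway_graph_tables(pathway)
  if (format == "json") {
    jsonlite::write_json(list(name = pathway$template$name,
                              nodes = g$nodes, edges = g$edges),
                         path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  attrs <- setdiff(names(g$nodes), "id")
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (i in seq_along(attrs)) {
    xml2::xml_add_child(doc, "key", id = paste0("d", i), "for" = "node",
                        attr.name = attrs[i], attr.type = "string")
  }
  xml2::xml_add_child(doc, "key", id = "e1", "for" = "edge",
                      attr.name = "role", attr.type = "string")
  graph <- xml2::xml_add_child(doc, "graph", id = pathway$template$name,
                               edgedefault = "directed")
  for (j in seq_len(nrow(g$nodes))) {
    node <- xml2::xml_add_child(graph, "node", id = g$nodes$id[j])
    for (i in seq_along(attrs)) {
      d <- xml2::xml_add_child(node, "data", key = paste0("d", i))
      xml2::xml_text(d) <- g$nodes[[attrs[i]]][j]
    }
  }
  for (j in seq_len(nrow(g$edges))) {
    edge <- xml2::xml_add_child(graph, "edge", source = g$edges$source[j],
                                target = g$edges$target[j])
    d <- xml2::xml_add_child(edge, "data", key = "e1")
    xml2::xml_text(d) <- g$edges$role[j]
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
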