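#' @include mining.R
NULL

#' Confidence and evidence network views
#'
#' Two star-shaped graphs around the query gene. The confidence view draws
#' one edge per associated gene, weighted by its overall association score
#' (a viewer may render higher-OAS edges wider/shorter; here the weight is
#' just a numeric edge attribute). The evidence view draws one labeled
#' edge per true evidence flag — a gene flagged under TFB and TFR gets two
#' parallel edges labeled TFB and TFR — and genes with no flags remain as
#' isolated nodes.
#'
#' @param result a [QueryResult-class] object.
#' @return an [AssociationGraph-class] object.
#' @export
confidenceView <- function(result) {
  stopifnot(is(result, "QueryResult"))
  rec <- result@records
  edges <- data.frame(from = rep(result@query, nrow(rec)), to = rec$gene,
                      label = rep("oas", nrow(rec)), weight = rec$oas,
                      stringsAsFactors = FALSE)
  new("AssociationGraph", viewKind = "confidence", query = result@query,
      nodes = c(result@query, rec$gene), edges = edges)
}

#' @rdname confidenceView
#' @export
evidenceView <- function(result) {
  stopifnot(is(result, "QueryResult"))
  rec <- result@records
  from <- to <- label <- character(0)
  for (ty in result@flagTypes) {
    flagged <- rec$gene[rec[[paste0("evidence.", ty)]]]
    from <- c(from, rep(result@query, length(flagged)))
    to <- c(to, flagged)
    label <- c(label, rep(ty, length(flagged)))
  }
  edges <- data.frame(from = from, to = to, label = label,
                      weight = rep(1, length(from)),
                      stringsAsFactors = FALSE)
  new("AssociationGraph", viewKind = "evidence", query = result@query,
      nodes = c(result@query, rec$gene), edges = edges)
}

## internal: igraph representation (undirected; keeps parallel edges)
asIgraph <- function(graph) {
  ed <- graph@edges
  igraph::graph_from_data_frame(
    ed[, c("from", "to", "label", "weight")],
    directed = FALSE,
    vertices = data.frame(name = graph@nodes, stringsAsFactors = FALSE))
}

#' Write a network view to file
#'
#' Supports the simple interaction format (SIF: `source TAB label TAB
#' target`, one line per edge, with the interaction label `"oas"` in the
#' confidence view and the evidence type code in the evidence view) and
#' GraphML (via igraph, carrying `label` and `weight` edge attributes).
#' Both load directly into Cytoscape; parallel evidence edges are
#' distinguished by their interaction label. Note SIF cannot represent
#' isolated nodes; GraphML preserves them.
#'
#' @param graph an [AssociationGraph-class] object.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeGraph <- function(graph, path, format = c("sif", "graphml")) {
  stopifnot(is(graph, "AssociationGraph"))
  format <- match.arg(format)
  if (format == "sif") {
    ed <- graph@edges
    writeLines(paste(ed$from, ed$label, ed$to, sep = "\t"), path)
  } else {
    igraph::write_graph(asIgraph(graph), path, format = "graphml")
  }
  invisible(path)
}
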