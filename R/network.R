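# AKI-centred disease network.
#
# A star graph with the AKI item as hub: one node per retained
# comorbidity partner, coloured by ICD-10 chapter and sized by
# importance = sup * kulc; edges carry kulc (width), lift (shade) and
# the verification status.

#' Build the AKI disease network
#'
#' Retains the `top_k` pairs by `sup * kulc` (lexicographic tie-break on
#' the partner code) and assembles the star graph.
#'
#' @param pairs AKI-centred `pair_rules` table.
#' @param verdicts Optional [validate_pairs()] output; edges then carry
#'   the `final` status, otherwise `"unknown"`.
#' @param top_k Number of pairs to retain (default 284, the size used
#'   for a readable network at full cohort scale); `top_k <= 0` yields a
#'   hub-only graph.
#' @return An `igraph` graph. Vertex attributes: `name` (code), `chapter`,
#'   `importance`; edge attributes: `kulc`, `lift`, `verified`.
#' @export
build_network <- function(pairs, verdicts = NULL, top_k = 284) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stop_config("pairs table is empty")
  partner <- ifelse(pairs$item_a == AKI_ITEM, pairs$item_b, pairs$item_a)
  imp <- pairs$sup * pairs$kulc
  ord <- order(-imp, partner)
  keep <- head(ord, max(top_k, 0))
  partner <- partner[keep]
  imp <- imp[keep]
  status <- rep("unknown", length(keep))
  if (!is.null(verdicts)) {
    v <- as.data.frame(verdicts)
    vp <- ifelse(v$item_a == AKI_ITEM, v$item_b, v$item_a)
    m <- match(partner, vp)
    status[!is.na(m)] <- v$final[m[!is.na(m)]]
  }
  vertices <- data.frame(
    name = c(AKI_ITEM, partner),
    chapter = c(chapter_of("N17"), chapter_of(partner)),
    importance = c(if (length(imp)) max(imp) else 1, imp),
    stringsAsFactors = FALSE
  )
  edges <- if (length(partner)) {
    data.frame(from = AKI_ITEM, to = partner,
               kulc = pairs$kulc[keep], lift = pairs$lift[keep],
               verified = status, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), kulc = numeric(),
               lift = numeric(), verified = character())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export a disease network
#'
#' @param graph An `igraph` graph from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"json"` (node-link).
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop_config("unknown format '%s'; supported: graphml, json",
                format[1]))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- as.data.frame(igraph::vertex_attr(graph),
                           stringsAsFactors = FALSE)
    eattrs <- igraph::edge_attr(graph)
    el <- igraph::as_edgelist(graph)
    links <- data.frame(from = el[, 1], to = el[, 2],
                        stringsAsFactors = FALSE)
    for (nm in names(eattrs)) links[[nm]] <- eattrs[[nm]]
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Import a disease network written by [export_graph()]
#'
#' @inheritParams export_graph
#' @return An `igraph` graph with all attributes restored.
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph stores its own "id" attribute on write; drop it
    if ("id" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "id")
    return(g)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(x$links, stringsAsFactors = FALSE)
  if (nrow(links) == 0)
    links <- data.frame(from = character(), to = character())
  igraph::graph_from_data_frame(links, directed = FALSE, vertices = nodes)
}
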