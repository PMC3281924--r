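#' Construct a bipartite TF-function network
#'
#' Nodes are transcription factors (with an expression-class attribute:
#' `embryo`, `endosperm`, `both` or `unclassified`) and annotation terms
#' (with a label); edges carry the enrichment q-value that linked them.
#'
#' @param tfs Tibble with columns `tf` and `class`.
#' @param terms Tibble with columns `term` and `label`.
#' @param edges Tibble with columns `tf`, `term`, `q`.
#' @return An [igraph::igraph] object with vertex attributes `type`
#'   (`"tf"`/`"term"`), `class`, `label`, and edge attribute `q`.
#' @export
tf_network <- function(tfs, terms, edges) {
  tfs <- tibble::as_tibble(tfs)
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    if (!all(edges$tf %in% tfs$tf) || !all(edges$term %in% terms$term)) {
      stop("edge endpoint missing from node tables", call. = FALSE)
    }
    if (any(edges$q <= 0 | edges$q > 1)) stop("edge q-values must be in (0, 1]", call. = FALSE)
  }
  if (any(tfs$tf %in% terms$term)) stop("tf and term ids must be disjoint", call. = FALSE)
  vertices <- dplyr::bind_rows(
    tibble::tibble(name = tfs$tf, type = "tf",
                   class = if ("class" %in% names(tfs)) tfs$class else "unclassified",
                   label = tfs$tf),
    tibble::tibble(name = terms$term, type = "term", class = NA_character_,
                   label = if ("label" %in% names(terms)) terms$label else terms$term)
  )
  igraph::graph_from_data_frame(
    d = edges[, intersect(c("tf", "term", "q"), names(edges)), drop = FALSE],
    directed = TRUE, vertices = vertices
  )
}

#' Export a TF-function network
#'
#' SIF dialect writes one edge per line, `TF<TAB>annotates<TAB>TERM`
#' (an empty network gives an empty file); GraphML (via igraph) carries the
#' node and edge attributes and re-imports with [igraph::read_graph()].
#'
#' @param net A [tf_network()] igraph.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  if (!inherits(net, "igraph")) stop("net must be an igraph object", call. = FALSE)
  format <- match.arg(format)
  if (format == "sif") {
    if (igraph::ecount(net) == 0) {
      writeLines(character(0), path)
    } else {
      ed <- igraph::as_data_frame(net, what = "edges")
      writeLines(paste(ed$from, "annotates", ed$to, sep = "\t"), path)
    }
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}
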