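#' Assemble a regulatory network from triads and cis pairs
#'
#' Builds node and edge tables for export. Edge relations are
#' \code{targets} (miRNA to regulator or mRNA), \code{coexpressed}
#' (regulator to mRNA, PCC gate), \code{sponges} (regulator to mRNA,
#' sponge-test summary) and \code{cis} (lncRNA to neighboring gene).
#'
#' @param triads data.frame from \code{\link{build_triads}} (may be
#'   empty).
#' @param cis_edges optional data.frame from \code{\link{de_cis_network}}.
#' @param classes named character vector feature id -> class (mRNA,
#'   lncRNA, circRNA, miRNA); unknown ids get \code{NA}.
#' @param directions named character vector feature id -> up/down.
#' @return List with data.frames \code{nodes} (\code{id}, \code{class},
#'   \code{direction}) and \code{edges} (\code{source}, \code{relation},
#'   \code{target}, \code{weight}).
#' @export
cerna_network <- function(triads, cis_edges = NULL, classes = NULL,
                          directions = NULL) {
  edges <- list()
  add <- function(source, relation, target, weight) {
    if (!length(source)) return()
    edges[[length(edges) + 1L]] <<- data.frame(
      source = source, relation = relation, target = target,
      weight = weight, stringsAsFactors = FALSE)
  }
  if (!is.null(triads) && nrow(triads)) {
    add(triads$mirna_id, "targets", triads$regulator_id,
        triads$scc_mi_regulator)
    add(triads$mirna_id, "targets", triads$mrna_id, triads$scc_mi_mrna)
    add(triads$regulator_id, "coexpressed", triads$mrna_id,
        triads$pcc_regulator_mrna)
    add(triads$regulator_id, "sponges", triads$mrna_id, triads$sponge_p)
  }
  if (!is.null(cis_edges) && nrow(cis_edges)) {
    add(cis_edges$lncrna_id, "cis", cis_edges$gene_id,
        as.numeric(cis_edges$gap_bp))
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(), relation = character(),
               target = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$relation, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.frame(
    id = ids,
    class = if (is.null(classes)) rep(NA_character_, length(ids))
    else unname(classes[ids]),
    direction = if (is.null(directions)) rep(NA_character_, length(ids))
    else unname(directions[ids]),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Export a network to SIF, GraphML or TSV
#'
#' SIF carries one \code{source relation target} line per edge (tab
#' separated); GraphML (via igraph) carries all node and edge attributes;
#' TSV writes \code{<path>} as the edge table and \code{<path>} with
#' suffix \code{.nodes.tsv} as the node table. GraphML and TSV re-import
#' losslessly via \code{\link{import_network}}.
#'
#' @param network list with \code{nodes} and \code{edges} as returned by
#'   \code{\link{cerna_network}}.
#' @param path output file path.
#' @param format one of \code{"SIF"}, \code{"GraphML"}, \code{"TSV"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(network, path, format = c("SIF", "GraphML",
                                                     "TSV")) {
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "TSV"))
    stop("unknown network format: ", format)
  format <- match.arg(format)
  nodes <- network$nodes; edges <- network$edges
  if (format == "SIF") {
    lines <- sprintf("%s\t%s\t%s", edges$source, edges$relation,
                     edges$target)
    isolated <- setdiff(nodes$id, c(edges$source, edges$target))
    writeLines(c(lines, isolated), path)
  } else if (format == "TSV") {
    write_tsv(edges, path)
    write_tsv(nodes, nodes_path(path))
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "relation", "weight")],
      directed = TRUE,
      vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a network written by \code{\link{export_network}}
#'
#' @param path file path.
#' @param format one of \code{"SIF"}, \code{"GraphML"}, \code{"TSV"}.
#' @return List with \code{nodes} and \code{edges} data.frames. SIF
#'   carries no attributes, so its nodes have \code{NA} class/direction
#'   and edges \code{NA} weight.
#' @export
import_network <- function(path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    full <- vapply(parts, length, integer(1)) == 3L
    edges <- data.frame(
      source = vapply(parts[full], `[`, "", 1L),
      relation = vapply(parts[full], `[`, "", 2L),
      target = vapply(parts[full], `[`, "", 3L),
      weight = rep(NA_real_, sum(full)), stringsAsFactors = FALSE)
    ids <- sort(unique(c(edges$source, edges$target,
                         unlist(parts[!full]))))
    nodes <- data.frame(id = ids,
                        class = rep(NA_character_, length(ids)),
                        direction = rep(NA_character_, length(ids)),
                        stringsAsFactors = FALSE)
  } else if (format == "TSV") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                               na.strings = "NA")
    nodes <- utils::read.delim(nodes_path(path), stringsAsFactors = FALSE,
                               na.strings = "NA")
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    nodes$id <- as.character(nodes$id)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name,
                        class = igraph::V(g)$class,
                        direction = igraph::V(g)$direction,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(source = el$from, relation = el$relation,
                        target = el$to, weight = el$weight,
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$source, edges$relation, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}

nodes_path <- function(path) sub("(\\.tsv)?$", ".nodes.tsv", path)

# deterministic TSV writer shared by all outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
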