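#' Construct an undirected protein-protein interaction graph
#'
#' Stores a simple undirected graph over gene symbols: self-loops are dropped,
#' both orientations of a pair collapse to one canonical edge (endpoints
#' sorted), and parallel edges are merged (keeping the maximum confidence
#' score where scores are present). The handshake lemma
#' (`sum(degree) == 2 * n_edges`) is asserted on construction.
#'
#' @param edges Two-column character matrix/data.frame of endpoints, or a
#'   data.frame with columns `from`, `to` and optionally `score`.
#' @param nodes Optional extra node names (isolated nodes are legal).
#' @param scores Optional integer confidence scores in `[0, 1000]`, one per
#'   edge row.
#' @return An object of class `ppi_graph` with fields `nodes` (sorted
#'   character) and `edges` (data.frame `from`, `to`, optional `score`).
#' @export
ppi_graph <- function(edges = NULL, nodes = NULL, scores = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    e <- data.frame(from = character(0), to = character(0),
                    stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (all(c("from", "to") %in% names(edges))) {
      a <- normalize_symbols(edges$from); b <- normalize_symbols(edges$to)
      if (is.null(scores) && "score" %in% names(edges)) scores <- edges$score
    } else {
      a <- normalize_symbols(edges[[1]]); b <- normalize_symbols(edges[[2]])
      if (is.null(scores) && ncol(edges) >= 3) scores <- edges[[3]]
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- lo != hi
    e <- data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE)
    if (!is.null(scores)) e$score <- as.numeric(scores)[keep]
    if (nrow(e)) {
      if (!is.null(scores)) {
        key <- paste(e$from, e$to, sep = "\r")
        e <- e[order(key, -e$score), , drop = FALSE]
        e <- e[!duplicated(paste(e$from, e$to, sep = "\r")), , drop = FALSE]
      } else {
        e <- unique(e)
      }
      e <- e[order(e$from, e$to), , drop = FALSE]
    }
    rownames(e) <- NULL
  }
  g <- structure(
    list(nodes = sort(unique(c(normalize_symbols(nodes %||% character(0)),
                               e$from, e$to))),
         edges = e),
    class = "ppi_graph")
  stopifnot(sum(graph_degree(g)) == 2L * n_edges(g))
  g
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph: %d nodes, %d edges>\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' @rdname ppi_graph
#' @param g A `ppi_graph`.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname ppi_graph
#' @export
n_edges <- function(g) nrow(g$edges)

#' Node degrees
#'
#' @param g A [ppi_graph()].
#' @return Named integer vector over all nodes (zeros for isolated nodes).
#' @export
graph_degree <- function(g) {
  d <- setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    t <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes))
    d[] <- as.integer(t)
  }
  d
}

# Adjacency as a list of integer neighbor indices, in node order.
adjacency_index <- function(g) {
  n <- length(g$nodes)
  if (!nrow(g$edges)) return(rep(list(integer(0)), n))
  i <- match(g$edges$from, g$nodes)
  j <- match(g$edges$to, g$nodes)
  unname(lapply(split(c(j, i), factor(c(i, j), levels = seq_len(n))),
                as.integer))
}

#' Read a STRING-style PPI edge list
#'
#' Whitespace- or tab-delimited columns `protein1 protein2 combined_score`;
#' the score column (integer, 0-1000) is optional. A header line starting
#' with `protein1` (any case) is skipped, as are blank and `#` comment lines.
#' Rows with `score < score_min` are dropped; both orientations of a pair
#' collapse to one edge and self-loops are removed.
#'
#' @param path Path to the edge-list file.
#' @param score_min Minimum combined score to keep an edge. Default 400,
#'   STRING's conventional "medium confidence" cut; ignored when the file has
#'   no score column. Set to 0 to keep everything.
#' @return A [ppi_graph()].
#' @export
read_ppi_edgelist <- function(path, score_min = 400) {
  if (!file.exists(path)) stop_format("I/O error: file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^protein1\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(ppi_graph())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop_format("PPI edge list parse error: fewer than 2 fields at line %d",
                which(nf < 2)[1])
  }
  m <- t(vapply(fields, function(f) f[1:3], character(3)))
  has_score <- all(nf >= 3)
  if (has_score) {
    if (any(!grepl("^[0-9]+$", m[, 3]))) {
      stop_format("PPI edge list parse error: non-integer score '%s' at line %d",
                  m[!grepl("^[0-9]+$", m[, 3]), 3][1],
                  which(!grepl("^[0-9]+$", m[, 3]))[1])
    }
    score <- as.integer(m[, 3])
    if (any(score < 0 | score > 1000)) {
      stop_format("PPI edge list parse error: score outside [0, 1000]")
    }
    keep <- score >= score_min
    ppi_graph(m[keep, 1:2, drop = FALSE], scores = score[keep])
  } else {
    ppi_graph(m[, 1:2, drop = FALSE])
  }
}

#' Serialize a PPI graph as an edge list
#'
#' Writes `protein1 protein2 [combined_score]` TSV, one canonical edge per
#' row. `read_ppi_edgelist()` on the result reproduces the graph
#' (round-trip idempotence).
#'
#' @param g A [ppi_graph()].
#' @param path Output path.
#' @export
write_ppi_edgelist <- function(g, path) {
  header <- if ("score" %in% names(g$edges)) {
    "protein1\tprotein2\tcombined_score"
  } else {
    "protein1\tprotein2"
  }
  body <- if (nrow(g$edges)) {
    do.call(paste, c(unname(as.list(g$edges)), sep = "\t"))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Restrict a PPI graph and drop isolated nodes
#'
#' Optionally restricts the graph to an induced subgraph on `keep` (e.g. the
#' drug-disease overlap genes), then removes all degree-0 nodes ("discrete
#' points"). Remaining edges — hence remaining nodes' degrees — are unchanged.
#'
#' @param g A [ppi_graph()].
#' @param keep Optional [gene_set()] or character vector; if supplied, only
#'   these nodes (and edges among them) are considered.
#' @return A [ppi_graph()] without isolated nodes.
#' @export
remove_isolated_nodes <- function(g, keep = NULL) {
  if (!is.null(keep)) {
    k <- as_gene_vector(keep)
    e <- g$edges[g$edges$from %in% k & g$edges$to %in% k, , drop = FALSE]
  } else {
    e <- g$edges
  }
  ppi_graph(e)
}

#' Rank nodes by degree
#'
#' Nodes sorted by degree descending, ties alphabetical — the "appearance
#' count" ranking used for a first look at PPI hubs.
#'
#' @param g A [ppi_graph()].
#' @return A `data.frame` with columns `gene`, `degree`.
#' @export
degree_rank_report <- function(g) {
  d <- graph_degree(g)
  out <- data.frame(gene = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the compound-target bipartite network
#'
#' Edges are exactly the target-map pairs restricted to the given compounds
#' and the given gene set; compounds (and genes) left with zero restricted
#' edges are dropped from the node sets. This is the network between active
#' compounds and the drug-disease overlap genes.
#'
#' @param map A [target_map()].
#' @param compounds Compound table (rows define the allowed compound ids).
#' @param genes A [gene_set()] or character vector of allowed gene symbols.
#' @return An object of class `bipartite_network` with fields
#'   `compound_nodes`, `gene_nodes` and `edges` (data.frame
#'   `compound_id`, `gene`).
#' @export
build_bipartite <- function(map, compounds, genes) {
  gv <- as_gene_vector(genes)
  ids <- unique(compounds$compound_id)
  e <- map[map$compound_id %in% ids & map$gene %in% gv, , drop = FALSE]
  e <- unique(as.data.frame(e, stringsAsFactors = FALSE))
  rownames(e) <- NULL
  structure(list(compound_nodes = sort(unique(e$compound_id)),
                 gene_nodes = sort(unique(e$gene)),
                 edges = e),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network: %d compounds, %d genes, %d edges>\n",
              length(x$compound_nodes), length(x$gene_nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a bipartite network in SIF-like form
#'
#' One `source <tab> interaction <tab> target` row per edge (interaction type
#' `targets`), plus an optional node-attribute table distinguishing compound
#' from gene nodes, for import into network viewers.
#'
#' @param net A [build_bipartite()] result.
#' @param path Output SIF path.
#' @param attr_path Optional node-attribute TSV path.
#' @export
write_sif <- function(net, path, attr_path = NULL) {
  writeLines(sprintf("%s\ttargets\t%s", net$edges$compound_id, net$edges$gene),
             path)
  if (!is.null(attr_path)) {
    attr <- rbind(
      data.frame(node = net$compound_nodes, type = "compound",
                 stringsAsFactors = FALSE),
      data.frame(node = net$gene_nodes, type = "gene",
                 stringsAsFactors = FALSE))
    utils::write.table(attr, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
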