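#' Degree centrality
#'
#' `dc(v) = |N(v)|`, the number of neighbors in the simple undirected graph.
#'
#' @param g A [ppi_graph()].
#' @return Named numeric vector over all nodes.
#' @export
degree_centrality <- function(g) {
  d <- graph_degree(g)
  storage.mode(d) <- "double"
  d
}

#' Betweenness centrality
#'
#' Shortest-path betweenness by Brandes' accumulation on the unweighted
#' graph: `bc(v)` sums, over node pairs `{s, t}` with `s != v != t`, the
#' fraction of shortest `s`-`t` paths passing through `v`. Pairs in different
#' components contribute 0. Unnormalized; by default each unordered pair is
#' counted once (`ordered_pairs = TRUE` counts both directions, doubling
#' every value).
#'
#' @param g A [ppi_graph()].
#' @param ordered_pairs Count ordered source-target pairs? Default `FALSE`.
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(g, ordered_pairs = FALSE) {
  n <- length(g$nodes)
  adj <- adjacency_index(g)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n); delta <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); queue[1] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    for (w in queue[tail:1]) {  # reverse BFS order
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (!ordered_pairs) bc <- bc / 2
  setNames(bc, g$nodes)
}

#' Closeness centrality
#'
#' Per-component normalization: within `v`'s connected component of size
#' `n_c`, `cc(v) = (n_c - 1) / sum of d(v, u)` over the other component
#' members. An isolated node gets 0. Values lie in `(0, 1]`, reaching 1 only
#' when `v` is adjacent to every other node of its component.
#'
#' @param g A [ppi_graph()].
#' @return Named numeric vector over all nodes.
#' @export
closeness_centrality <- function(g) {
  n <- length(g$nodes)
  adj <- adjacency_index(g)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- integer(n); queue[1] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
      }
    }
    reach <- which(dist > 0L)
    cc[s] <- if (length(reach)) length(reach) / sum(dist[reach]) else 0
  }
  setNames(cc, g$nodes)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix, computed by power iteration
#' on the diagonally shifted matrix `A + I` (same eigenvectors as `A`, but a
#' strictly dominant top eigenvalue, so the iteration also converges on
#' bipartite graphs whose extreme eigenvalues are symmetric). Entries are
#' non-negative and the vector has unit Euclidean norm over all nodes.
#' Convergence requires the successive-iterate maximum difference to fall
#' below `tol`; exceeding `max_iter` is an explicit error, never a silent
#' partial result.
#'
#' @param g A [ppi_graph()] with at least one edge.
#' @param tol Convergence tolerance. Default `1e-10`.
#' @param max_iter Iteration cap. Default `10000`.
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000) {
  n <- length(g$nodes)
  if (!nrow(g$edges)) {
    stop_format("eigenvector centrality undefined: graph has no edges")
  }
  i <- match(g$edges$from, g$nodes)
  j <- match(g$edges$to, g$nodes)
  A <- matrix(0, n, n)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      return(setNames(y, g$nodes))
    }
    x <- y
  }
  stop_format("eigenvector centrality failed to converge within %d iterations (tol %g)",
              max_iter, tol)
}

#' Local average connectivity (LAC)
#'
#' `lac(v)` is the mean degree, within the subgraph induced by `v`'s
#' neighborhood `N(v)`, of the members of `N(v)`; equivalently
#' `2 * E(N(v)) / |N(v)|` where `E(N(v))` counts edges among the neighbors.
#' Zero for isolated nodes and for neighborhoods inducing no edges.
#'
#' @param g A [ppi_graph()].
#' @return Named numeric vector over all nodes.
#' @export
local_average_connectivity <- function(g) {
  n <- length(g$nodes)
  adj <- adjacency_index(g)
  lac <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb)) {
      induced_degree_sum <- sum(vapply(
        nb, function(w) sum(adj[[w]] %in% nb), integer(1)))
      lac[v] <- induced_degree_sum / length(nb)
    }
  }
  setNames(lac, g$nodes)
}

#' Network centrality (NC)
#'
#' Sum over `v`'s incident edges of the edge clustering coefficient
#' `ECC(u, w) = z / min(deg(u) - 1, deg(w) - 1)`, where `z` counts common
#' neighbors of `u` and `w` (triangles on the edge). When the denominator is
#' 0 (an endpoint of degree 1), the ECC of that edge is taken as 0 by
#' default; `ecc_degenerate = "one"` switches to the alternative convention
#' of assigning such edges an ECC of 1.
#'
#' @param g A [ppi_graph()].
#' @param ecc_degenerate Value convention for degenerate denominators,
#'   `"zero"` (default) or `"one"`.
#' @return Named numeric vector over all nodes.
#' @export
network_centrality <- function(g, ecc_degenerate = c("zero", "one")) {
  ecc_degenerate <- match.arg(ecc_degenerate)
  n <- length(g$nodes)
  adj <- adjacency_index(g)
  deg <- lengths(adj)
  nc <- numeric(n)
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    for (k in seq_along(i)) {
      u <- i[k]; w <- j[k]
      denom <- min(deg[u], deg[w]) - 1L
      ecc <- if (denom <= 0L) {
        if (ecc_degenerate == "one") 1 else 0
      } else {
        sum(adj[[u]] %in% adj[[w]]) / denom
      }
      nc[u] <- nc[u] + ecc
      nc[w] <- nc[w] + ecc
    }
  }
  setNames(nc, g$nodes)
}

#' Compute all six centrality measures
#'
#' One table with degree (DC), betweenness (BC), closeness (CC), eigenvector
#' (EC), local average connectivity (LAC) and network centrality (NC) per
#' node — the topology profile used for consensus hub selection. Eigenvector
#' non-convergence propagates as an error.
#'
#' @param g A [ppi_graph()] with at least one edge.
#' @inheritParams eigenvector_centrality
#' @return A `data.frame` (class `centrality_table`) with columns `node`,
#'   `dc`, `bc`, `cc`, `ec`, `lac`, `nc`, one row per node, alphabetical.
#' @export
compute_all_centralities <- function(g, tol = 1e-10, max_iter = 10000) {
  out <- data.frame(node = g$nodes,
                    dc = unname(degree_centrality(g)),
                    bc = unname(betweenness_centrality(g)),
                    cc = unname(closeness_centrality(g)),
                    ec = unname(eigenvector_centrality(g, tol, max_iter)),
                    lac = unname(local_average_connectivity(g)),
                    nc = unname(network_centrality(g)),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

centrality_metrics <- c("dc", "bc", "cc", "ec", "lac", "nc")

#' Median-consensus hub selection
#'
#' Retains the nodes that meet the per-metric median on all six centrality
#' measures simultaneously. Medians default to the medians of the supplied
#' table (even row counts use the mean of the two middle values); externally
#' computed medians — e.g. medians taken over a larger network than the rows
#' at hand — may be passed instead. The comparison rule is inclusive (`>=`)
#' by default or strict (`>`).
#'
#' @param table A [compute_all_centralities()] table (columns `node` plus the
#'   six metrics).
#' @param rule `"inclusive"` or `"strict"`.
#' @param medians Optional named numeric vector with entries `dc`, `bc`,
#'   `cc`, `ec`, `lac`, `nc`.
#' @return A `hub_selection` list with fields `medians`, `retained` (gene
#'   symbols ordered by `dc` descending, ties alphabetical), `rule`, `table`
#'   (the retained rows).
#' @export
median_filter <- function(table, rule = c("inclusive", "strict"),
                          medians = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(centrality_metrics %in% names(table)))
  if (is.null(medians)) {
    medians <- vapply(centrality_metrics,
                      function(m) stats::median(table[[m]]), numeric(1))
  } else {
    missing <- setdiff(centrality_metrics, names(medians))
    if (length(missing)) {
      stop_format("medians must name all six metrics; missing: %s",
                  paste(missing, collapse = ", "))
    }
    medians <- medians[centrality_metrics]
  }
  cmp <- if (rule == "inclusive") `>=` else `>`
  ok <- Reduce(`&`, lapply(centrality_metrics,
                           function(m) cmp(table[[m]], medians[[m]])))
  kept <- table[ok, , drop = FALSE]
  kept <- kept[order(-kept$dc, kept$node), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(medians = medians, retained = kept$node, rule = rule,
                 table = kept),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("<hub_selection (%s rule): %d nodes retained>\n",
              x$rule, length(x$retained)))
  cat(" medians:",
      paste(sprintf("%s=%.4g", names(x$medians), x$medians), collapse = ", "),
      "\n")
  if (length(x$retained)) cat(" ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

# Bron-Kerbosch maximal-clique enumeration with pivoting, integer index sets.
enumerate_maximal_cliques <- function(adj, n, max_cliques = 1e6) {
  cliques <- vector("list", 64L)
  count <- 0L
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      count <<- count + 1L
      if (count > max_cliques) {
        stop_format("maximal clique enumeration exceeded the cap of %g cliques",
                    max_cliques)
      }
      if (count > length(cliques)) {
        length(cliques) <<- 2L * length(cliques)
      }
      cliques[[count]] <<- R
      return(invisible(NULL))
    }
    px <- c(P, X)
    u <- px[which.max(vapply(px, function(v) sum(P %in% adj[[v]]),
                             integer(1)))]
    for (v in setdiff(P, adj[[u]])) {
      bk(c(R, v), P[P %in% adj[[v]]], X[X %in% adj[[v]]])
      P <- P[P != v]
      X <- c(X, v)
    }
    invisible(NULL)
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques[seq_len(count)]
}

#' Maximal clique centrality (MCC)
#'
#' `mcc(v)` sums `(|C| - 1)!` over all maximal cliques `C` containing `v`,
#' enumerated by Bron-Kerbosch with pivoting. Large cliques dominate the
#' score, favoring densely interconnected hubs. A node whose neighborhood
#' induces no edges scores exactly its degree (each incident edge is a
#' maximal 2-clique contributing `1! = 1`); an isolated node scores 0.
#' Counts are exact integers (factorials up to 18! are exactly representable
#' in doubles; PPI cliques are far smaller).
#'
#' @param g A [ppi_graph()].
#' @param max_cliques Guard against clique-count explosion: enumeration
#'   aborts with an error beyond this many maximal cliques. Default `1e6`.
#' @return A `data.frame` (class `mcc_ranking`) with columns `node`, `mcc`,
#'   `dc`, one row per node, alphabetical.
#' @export
mcc <- function(g, max_cliques = 1e6) {
  n <- length(g$nodes)
  adj <- adjacency_index(g)
  scores <- numeric(n)
  if (n > 0) {
    cliques <- enumerate_maximal_cliques(adj, n, max_cliques)
    for (cl in cliques) {
      if (length(cl) >= 2) {  # single vertices are not counted
        scores[cl] <- scores[cl] + factorial(length(cl) - 1)
      }
    }
  }
  out <- data.frame(node = g$nodes, mcc = scores,
                    dc = as.integer(lengths(adj)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mcc_ranking", "data.frame")
  out
}

#' Top-k nodes of an MCC ranking
#'
#' The k highest-MCC nodes; ties are broken by higher degree, then
#' alphabetically by symbol. The `tied` column records whether a node's MCC
#' value is shared with any node outside the selection, so tie-break-driven
#' selections are visible in the output.
#'
#' @param ranking A [mcc()] result.
#' @param k Positive integer, at most the node count.
#' @return A `data.frame` with columns `rank`, `node`, `mcc`, `dc`, `tied`.
#' @export
top_k <- function(ranking, k) {
  stopifnot(is.data.frame(ranking), k >= 1, k <= nrow(ranking))
  ord <- ranking[order(-ranking$mcc, -ranking$dc, ranking$node), ,
                 drop = FALSE]
  sel <- ord[seq_len(k), , drop = FALSE]
  boundary_tie <- if (k < nrow(ord)) sel$mcc == ord$mcc[k + 1] else
    rep(FALSE, k)
  out <- data.frame(rank = seq_len(k), node = sel$node, mcc = sel$mcc,
                    dc = sel$dc, tied = boundary_tie,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
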