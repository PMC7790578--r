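# Brute-force oracles, written independently of the package's algorithms:
# Floyd-Warshall distances, exhaustive simple-path enumeration for
# betweenness, dense eigendecomposition, adjacency-matrix recounts for LAC
# and NC, and subset enumeration for maximal cliques. Only usable on small
# graphs, which is the point.

oracle_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    A[cbind(g$edges$from, g$edges$to)] <- 1
    A[cbind(g$edges$to, g$edges$from)] <- 1
  }
  A
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_degree <- function(g) rowSums(oracle_adjacency(g))

oracle_closeness <- function(g) {
  D <- oracle_distances(oracle_adjacency(g))
  vapply(seq_len(nrow(D)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1)) |> setNames(g$nodes)
}

# all simple paths s -> t, then keep the shortest ones
oracle_all_shortest_paths <- function(A, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in which(A[v, ] > 0)) {
      if (!(w %in% path)) rec(c(path, w))
    }
    invisible(NULL)
  }
  rec(s)
  if (!length(paths)) return(list())
  lens <- lengths(paths)
  paths[lens == min(lens)]
}

oracle_betweenness <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  bc <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        sp <- oracle_all_shortest_paths(A, s, t)
        if (!length(sp)) next
        inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
        if (length(inner)) {
          tb <- table(inner)
          idx <- as.integer(names(tb))
          bc[idx] <- bc[idx] + as.numeric(tb) / length(sp)
        }
      }
    }
  }
  setNames(bc, g$nodes)
}

# principal eigenvector by dense symmetric eigendecomposition; returns NULL
# when the top eigenvalue is (numerically) degenerate and the principal
# direction is not unique
oracle_eigenvector <- function(g) {
  A <- oracle_adjacency(g)
  e <- eigen(A, symmetric = TRUE)
  if (nrow(A) > 1 && e$values[1] - e$values[2] < 1e-8) return(NULL)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  setNames(v / sqrt(sum(v^2)), g$nodes)
}

oracle_lac <- function(g) {
  A <- oracle_adjacency(g)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (!length(nb)) 0 else sum(A[nb, nb, drop = FALSE]) / length(nb)
  }, numeric(1)) |> setNames(g$nodes)
}

oracle_nc <- function(g) {
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  n <- nrow(A)
  nc <- numeric(n)
  for (u in seq_len(n)) {
    for (w in seq_len(n)) {
      if (w > u && A[u, w] > 0) {
        z <- sum(A[u, ] > 0 & A[w, ] > 0)
        den <- min(deg[u], deg[w]) - 1
        ecc <- if (den <= 0) 0 else z / den
        nc[u] <- nc[u] + ecc
        nc[w] <- nc[w] + ecc
      }
    }
  }
  setNames(nc, g$nodes)
}

oracle_mcc <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  scores <- numeric(n)
  if (n >= 2) {
    for (mask in seq_len(2^n - 1)) {
      members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(members) < 2) next
      pairs <- utils::combn(members, 2)
      if (!all(A[t(pairs)] > 0)) next
      outside <- setdiff(seq_len(n), members)
      maximal <- !any(vapply(outside, function(o) all(A[o, members] > 0),
                             logical(1)))
      if (maximal) {
        scores[members] <- scores[members] + factorial(length(members) - 1)
      }
    }
  }
  setNames(scores, g$nodes)
}

# exhaustive hypergeometric upper tail by enumerating every size-n draw
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# random labelled graph on n nodes, edges i.i.d. Bernoulli(p)
random_test_graph <- function(n, p, seed, connected = FALSE) {
  with_test_seed(seed, {
    repeat {
      pairs <- t(utils::combn(LETTERS[seq_len(n)], 2))
      keep <- stats::runif(nrow(pairs)) < p
      g <- ppi_graph(pairs[keep, , drop = FALSE],
                     nodes = LETTERS[seq_len(n)])
      if (!connected) return(g)
      D <- oracle_distances(oracle_adjacency(g))
      if (all(is.finite(D))) return(g)
    }
  })
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# complete graph on the given labels
complete_graph <- function(labels) {
  ppi_graph(t(utils::combn(labels, 2)))
}

# star with given center and leaves
star_graph <- function(center = "A", leaves = c("B", "C", "D", "E")) {
  ppi_graph(cbind(center, leaves))
}

expect_named_equal <- function(actual, expected, tol = 1e-9) {
  expect_equal(actual[sort(names(actual))],
               expected[sort(names(expected))],
               tolerance = tol)
}
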