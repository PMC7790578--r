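# Closed-form cases first, then oracle agreement on exhaustive small graphs
# and random graphs, then the consensus filter and MCC ranking logic.

test_that("centralities reproduce closed forms on canonical graphs", {
  k5 <- complete_graph(LETTERS[1:5])
  tab <- compute_all_centralities(k5)
  expect_true(all(tab$dc == 4))
  expect_true(all(tab$bc == 0))
  expect_true(all(tab$cc == 1))
  expect_equal(tab$ec, rep(1 / sqrt(5), 5), tolerance = 1e-8)
  expect_true(all(tab$lac == 3))
  expect_true(all(tab$nc == 4))  # 4 incident edges, each ECC = 3/3

  star <- star_graph()
  expect_equal(unname(betweenness_centrality(star)["A"]), choose(4, 2))
  expect_true(all(betweenness_centrality(star)[-1] == 0))
  expect_equal(unname(closeness_centrality(star)["B"]), 4 / 7,
               tolerance = 1e-12)
  ec <- eigenvector_centrality(star)
  expect_equal(unname(ec["A"]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(ec["B"]), 1 / (2 * sqrt(2)), tolerance = 1e-8)
  expect_equal(unname(local_average_connectivity(star)["A"]), 0)
  expect_true(all(network_centrality(star) == 0))

  tri <- complete_graph(c("X", "Y", "Z"))
  expect_true(all(local_average_connectivity(tri) == 1))
  expect_true(all(network_centrality(tri) == 2))

  k4 <- complete_graph(LETTERS[1:4])
  expect_true(all(network_centrality(k4) == 3))

  edge <- ppi_graph(rbind(c("A", "B")))
  etab <- compute_all_centralities(edge)
  expect_equal(etab$dc, c(1, 1))
  expect_equal(etab$cc, c(1, 1))
  expect_equal(etab$ec, rep(1 / sqrt(2), 2), tolerance = 1e-8)
})

test_that("degenerate-denominator ECC convention is switchable", {
  path <- ppi_graph(rbind(c("A", "B"), c("B", "C")))
  expect_true(all(network_centrality(path) == 0))
  alt <- network_centrality(path, ecc_degenerate = "one")
  # both edges have a degree-1 endpoint; convention assigns each ECC 1
  expect_equal(unname(alt), c(1, 2, 1))
})

test_that("eigenvector centrality fails loudly when not converged", {
  expect_error(eigenvector_centrality(star_graph(), max_iter = 1),
               "converge")
  expect_error(eigenvector_centrality(ppi_graph(nodes = c("A", "B"))),
               "no edges")
  # bipartite spectra (symmetric +/- eigenvalues) still converge
  expect_silent(eigenvector_centrality(star_graph()))
})

test_that("all six centralities and MCC agree with brute force on every 4-node graph", {
  labels <- LETTERS[1:4]
  pairs <- t(utils::combn(labels, 2))
  for (mask in 0:63) {
    keep <- bitwAnd(mask, 2^(0:5)) > 0
    g <- ppi_graph(pairs[keep, , drop = FALSE], nodes = labels)
    expect_equal(degree_centrality(g), oracle_degree(g))
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-12)
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-12)
    expect_equal(local_average_connectivity(g), oracle_lac(g),
                 tolerance = 1e-12)
    expect_equal(network_centrality(g), oracle_nc(g), tolerance = 1e-12)
    mm <- mcc(g)
    expect_equal(setNames(mm$mcc, mm$node), oracle_mcc(g))
    if (n_edges(g) > 0) {
      ref <- oracle_eigenvector(g)
      if (!is.null(ref)) {
        expect_equal(eigenvector_centrality(g), ref, tolerance = 1e-6)
      }
    }
  }
})

test_that("centralities agree with brute force on random 5-8 node graphs", {
  for (seed in 1:25) {
    n <- 5 + (seed %% 4)
    g <- random_test_graph(n, 0.25 + 0.5 * (seed %% 3) / 2, seed)
    expect_equal(degree_centrality(g), oracle_degree(g))
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-12)
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-12)
    expect_equal(local_average_connectivity(g), oracle_lac(g),
                 tolerance = 1e-12)
    expect_equal(network_centrality(g), oracle_nc(g), tolerance = 1e-12)
    mm <- mcc(g)
    expect_equal(setNames(mm$mcc, mm$node), oracle_mcc(g))
    if (n_edges(g) > 0) {
      ec <- eigenvector_centrality(g)
      expect_true(all(ec >= -1e-12))
      expect_equal(sum(ec^2), 1, tolerance = 1e-9)
      ref <- oracle_eigenvector(g)
      if (!is.null(ref)) expect_equal(ec, ref, tolerance = 1e-6)
    }
  }
})

test_that("centralities cross-check against an independent graph library", {
  for (seed in c(3, 7, 11)) {
    g <- random_test_graph(8, 0.5, seed, connected = TRUE)
    ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, c("from", "to")]),
                                      directed = FALSE)
    perm <- match(igraph::V(ig)$name, g$nodes)
    expect_equal(unname(betweenness_centrality(g))[perm],
                 unname(igraph::betweenness(ig)), tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(g))[perm],
                 unname(igraph::closeness(ig, normalized = TRUE)),
                 tolerance = 1e-9)
    ig_ec <- igraph::eigen_centrality(ig)$vector
    ig_ec <- ig_ec / sqrt(sum(ig_ec^2))
    expect_equal(unname(eigenvector_centrality(g))[perm], unname(ig_ec),
                 tolerance = 1e-6)
  }
})

test_that("median consensus filter retains nodes above every median", {
  tab <- data.frame(node = paste0("g", 1:5),
                    dc = c(10, 8, 6, 4, 2),
                    bc = c(5, 4, 3, 2, 1),
                    cc = c(0.9, 0.8, 0.7, 0.6, 0.5),
                    ec = c(0.5, 0.4, 0.3, 0.2, 0.1),
                    lac = c(3, 2.5, 2, 1.5, 1),
                    nc = c(6, 5, 4, 3, 2))
  # sort-based oracle for the medians
  med_oracle <- vapply(c("dc", "bc", "cc", "ec", "lac", "nc"), function(m) {
    v <- sort(tab[[m]])
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  }, numeric(1))
  sel <- median_filter(tab)
  expect_equal(unname(sel$medians), unname(med_oracle))
  expect_equal(sel$retained, c("g1", "g2", "g3"))
  strict <- median_filter(tab, rule = "strict")
  expect_equal(strict$retained, c("g1", "g2"))

  # a node maximal in every metric is always retained
  for (seed in 1:10) {
    with_test_seed(seed, {
      rt <- data.frame(node = paste0("g", 1:9),
                       dc = sample(1:50, 9), bc = runif(9, 0, 100),
                       cc = runif(9), ec = runif(9), lac = runif(9, 0, 5),
                       nc = runif(9, 0, 10))
      rt[1, -1] <- lapply(rt[-1, -1], max)
      expect_true("g1" %in% median_filter(rt)$retained)
    })
  }
})

test_that("consensus filter rarely exceeds half the table on independent metrics", {
  for (seed in 1:50) {
    with_test_seed(seed, {
      n <- 15
      rt <- data.frame(node = sprintf("g%02d", 1:n),
                       dc = runif(n), bc = runif(n), cc = runif(n),
                       ec = runif(n), lac = runif(n), nc = runif(n))
      expect_lte(length(median_filter(rt)$retained), ceiling(n / 2))
    })
  }
})

test_that("external medians can drive the consensus filter", {
  tab <- data.frame(node = c("a", "b"), dc = c(5, 1), bc = c(5, 1),
                    cc = c(0.5, 0.1), ec = c(0.5, 0.1), lac = c(5, 1),
                    nc = c(5, 1))
  meds <- c(dc = 2, bc = 2, cc = 0.2, ec = 0.2, lac = 2, nc = 2)
  expect_equal(median_filter(tab, medians = meds)$retained, "a")
  expect_error(median_filter(tab, medians = meds[-1]), "missing")
  # retained set is ordered by degree descending
  tab2 <- rbind(tab, data.frame(node = "c", dc = 9, bc = 9, cc = 0.9,
                                ec = 0.9, lac = 9, nc = 9))
  expect_equal(median_filter(tab2, medians = meds)$retained, c("c", "a"))
})

test_that("MCC counts maximal cliques with factorial weights", {
  k5 <- mcc(complete_graph(LETTERS[1:5]))
  expect_true(all(k5$mcc == 24))

  star <- mcc(star_graph())
  expect_equal(star$mcc[star$node == "A"], 4)  # equals its degree
  expect_true(all(star$mcc[star$node != "A"] == 1))

  # two triangles sharing one vertex
  bowtie <- ppi_graph(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                            c("C", "D"), c("D", "E"), c("C", "E")))
  bt <- mcc(bowtie)
  expect_equal(bt$mcc[bt$node == "C"], 4)
  expect_true(all(bt$mcc[bt$node != "C"] == 2))

  # every component a clique: mcc = (component size - 1)!
  dis <- ppi_graph(rbind(t(utils::combn(c("A", "B", "C", "D"), 2)),
                         c("X", "Y")))
  dd <- mcc(dis)
  expect_true(all(dd$mcc[dd$node %in% c("A", "B", "C", "D")] == 6))
  expect_true(all(dd$mcc[dd$node %in% c("X", "Y")] == 1))

  # isolated node scores zero
  iso <- mcc(ppi_graph(rbind(c("A", "B")), nodes = c("A", "B", "Z")))
  expect_equal(iso$mcc[iso$node == "Z"], 0)

  # enumeration guard trips on demand
  expect_error(mcc(star_graph(), max_cliques = 2), "cap")
})

test_that("top_k ranks by MCC with degree and name tie-breaks", {
  g <- ppi_graph(rbind(t(utils::combn(LETTERS[1:5], 2)), c("F", "G")))
  top <- top_k(mcc(g), 5)
  expect_setequal(top$node, LETTERS[1:5])

  flat <- mcc(ppi_graph(rbind(c("B", "D"), c("A", "C"))))
  expect_equal(top_k(flat, 2)$node, c("A", "B"))  # alphabetical prefix
  expect_true(all(top_k(flat, 2)$tied))

  expect_error(top_k(flat, 9), "k <= ")
})
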