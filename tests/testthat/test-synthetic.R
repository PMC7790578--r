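test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 11)
  a <- gen_compound_table(cfg)
  b <- gen_compound_table(cfg)
  expect_identical(a, b)
  ta <- gen_target_map(cfg, a$records)
  tb <- gen_target_map(cfg, a$records)
  expect_identical(ta, tb)
  pa <- gen_ppi(cfg)
  pb <- gen_ppi(cfg)
  expect_identical(pa, pb)
  ga <- gen_annotations(cfg, sprintf("Q%02d", 1:15))
  gb <- gen_annotations(cfg, sprintf("Q%02d", 1:15))
  expect_identical(ga, gb)
  # a different seed changes the draw
  expect_false(identical(a, gen_compound_table(sim_config(seed = 12))))
})

test_that("compound generator matches its manifest and the expected pass rate", {
  cfg <- sim_config(seed = 2, n_compounds = c(50, 50))
  out <- gen_compound_table(cfg)
  expect_equal(nrow(out$records), 100)
  # manifest is exactly what the filter recomputes (closed loop)
  act <- adme_filter(out$records, cfg$ob_min, cfg$dl_min)
  expect_setequal(act$compound_id,
                  out$manifest$compound_id[out$manifest$passes])
  # uniform OB on [0,100] and DL on [0,1]: P(pass) = 0.70 * 0.82 = 0.574
  rates <- vapply(1:20, function(s) {
    m <- gen_compound_table(sim_config(seed = s, n_compounds = c(50, 50)))
    mean(m$manifest$passes)
  }, numeric(1))
  expect_equal(mean(rates), 0.574, tolerance = 0.035)

  # an OB range capped below the threshold passes nothing
  none <- gen_compound_table(sim_config(seed = 3, ob_range = c(0, 29)))
  expect_equal(sum(none$manifest$passes), 0)
})

test_that("target map generator plants herb pools, overlap and disease overlap", {
  cfg <- sim_config(seed = 4)
  comp <- gen_compound_table(cfg)
  tm <- gen_target_map(cfg, comp$records)
  sets <- lapply(tm$manifest$herb_targets, gene_set)
  expect_equal(length(sets[[1]]), 13)
  expect_equal(length(sets[[2]]), 41)
  rep2 <- set_intersection_report(sets[[1]], sets[[2]])
  expect_equal(rep2$n_intersection, 7)
  expect_equal(rep2$n_union, 47)
  # running the pipeline stage recovers the manifest sets (closed loop)
  for (i in 1:2) {
    herb <- cfg$herbs[i]
    got <- targets_of_herb(tm$map,
                           comp$records[comp$records$herb == herb, ])
    expect_equal(got$genes, tm$manifest$herb_targets[[herb]])
  }
  # mapped compounds all pass the screen, and number 6 + 10
  expect_equal(length(tm$manifest$mapped_compounds), 16)
  passers <- comp$manifest$compound_id[comp$manifest$passes]
  expect_true(all(tm$manifest$mapped_compounds %in% passers))
  # disease list carries exactly the planted drug overlap
  ov <- drug_disease_overlap(gene_set(tm$manifest$drug_targets, "drug"),
                             tm$disease)
  expect_equal(ov$genes, tm$manifest$disease_overlap_genes)
  expect_equal(length(ov), 44)
  expect_equal(length(tm$disease), 7153)
  # pair count equals the de-duplicated map size
  expect_equal(tm$manifest$n_pairs, nrow(tm$map))

  # zero mapped compounds -> empty map
  cfg0 <- sim_config(seed = 4, mapped_per_herb = c(0, 0),
                     planted_overlap = 0)
  tm0 <- gen_target_map(cfg0, comp$records)
  expect_equal(nrow(tm0$map), 0)
})

test_that("PPI generator plants a recoverable clique on a heavy-tailed backbone", {
  cfg <- sim_config(seed = 6)
  out <- gen_ppi(cfg)
  g <- out$graph
  expect_equal(n_nodes(g), 40)
  expect_equal(sum(graph_degree(g)), 2 * n_edges(g))
  # the planted 6-clique occupies the MCC top 6
  expect_setequal(top_k(mcc(g), 6)$node, out$manifest$clique_members)
  # attachment 1 with no clique gives a triangle-free tree
  tree <- gen_ppi(sim_config(seed = 6, ppi_attachment = 1,
                             planted_clique_size = 0))$graph
  expect_equal(n_edges(tree), n_nodes(tree) - 1)
  expect_true(all(local_average_connectivity(tree) == 0))
  expect_true(all(network_centrality(tree) == 0))
  # degree distribution is right-skewed (hub-dominated)
  d <- graph_degree(out$graph)
  expect_gt(max(d), 3 * stats::median(d))
})

test_that("annotation generator plants one enriched term inside the universe", {
  query <- sprintf("Q%02d", 1:15)
  cfg <- sim_config(seed = 8)
  out <- gen_annotations(cfg, query)
  col <- out$collection
  expect_equal(length(col$terms), 50)
  expect_equal(length(col$universe), 2000)
  planted <- col$terms[[out$manifest$planted_term]]
  expect_equal(length(planted$genes), 40)
  expect_equal(sum(query %in% planted$genes), 10)
  expect_true(all(unlist(lapply(col$terms, `[[`, "genes")) %in%
                    col$universe))
  # a term equal to the query is the minimal-p term among all terms
  cfg_min <- sim_config(seed = 8, planted_term_size = 15,
                        planted_term_hits = 15)
  res <- ora(query, gen_annotations(cfg_min, query)$collection)
  expect_equal(res$term_id[1], "T050")
  expect_equal(res$p[1], min(res$p))
})

test_that("synthetic bundles serialize losslessly", {
  dir <- tempfile("bundle_")
  cfg <- sim_config(seed = 9)
  objs <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("compounds.tsv", "target_map.tsv", "disease_genes.txt",
           "ppi_edges.tsv", "annotations.gmt", "manifest.json")))))
  tab <- read_compound_table(file.path(dir, "compounds.tsv"))
  expect_equal(nrow(tab), sum(cfg$n_compounds))
  m <- read_target_map(file.path(dir, "target_map.tsv"))
  expect_equal(nrow(m), objs$targets$manifest$n_pairs)
  g <- read_ppi_edgelist(file.path(dir, "ppi_edges.tsv"), score_min = 0)
  expect_equal(n_edges(g), n_edges(objs$ppi$graph))
  col <- read_gmt(file.path(dir, "annotations.gmt"))
  expect_equal(length(col$terms), cfg$n_terms)
})
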