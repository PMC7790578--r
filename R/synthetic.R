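#' Simulation configuration
#'
#' Parameters for the synthetic-data generators that emulate the database
#' pulls a network-pharmacology study performs (compound tables, target
#' lookups, disease gene collections, PPI subnetworks, annotation sets),
#' each with recorded ground truth. Defaults mirror the study conditions of
#' a two-herb screen: 65 + 116 candidate compounds (typical database pull
#' sizes for a root/rhizome herb pair), OB uniform on 0-100 % and DL uniform
#' on 0-1 screened at OB >= 30 / DL >= 0.18, 6 + 10 mapped
#' compounds with per-herb target pools of 13 and 41 genes sharing 7, a
#' disease collection of 7,153 genes from a 10,000-gene universe planted
#' with 44 drug targets, a 40-node preferential-attachment PPI backbone
#' (2 edges per arriving node) with one planted 6-clique, and 50 annotation
#' terms over a 2,000-gene universe with one planted enriched term (size 40,
#' 10 query hits against a query of 15).
#'
#' @param seed Integer RNG seed; every generator is a pure function of the
#'   config (stage seeds are derived as `seed`, `seed + 1`, ...).
#' @param herbs Herb labels.
#' @param n_compounds Candidate compounds per herb.
#' @param ob_range,dl_range Uniform ranges for the OB and DL descriptors.
#' @param ob_min,dl_min ADME thresholds recorded in the manifest.
#' @param mapped_per_herb Screen-passing compounds per herb with at least
#'   one target (the rest emulate database misses and map to nothing);
#'   mapping only ever draws from compounds that pass the ADME screen, as
#'   target lookup follows screening.
#' @param targets_per_compound Mean of the (zero-truncated Poisson) number of
#'   targets drawn per mapped compound.
#' @param herb_target_sizes Per-herb target-pool sizes.
#' @param herb_overlap Genes shared between the two herb pools.
#' @param gene_universe_size Size of the gene universe symbols are drawn from.
#' @param disease_gene_count Size of the disease gene collection.
#' @param planted_overlap Drug targets planted into the disease collection.
#' @param ppi_nodes,ppi_attachment Preferential-attachment graph size and
#'   edges added per arriving node (`1` yields a tree).
#' @param planted_clique_size Clique planted into the PPI backbone (0 = none).
#' @param n_terms,term_size_range Background annotation terms and their size
#'   range.
#' @param planted_term_size,planted_term_hits Size of the planted enriched
#'   term and how many query genes it receives.
#' @param query_size Query size used when the pipeline generates its own
#'   query.
#' @param annotation_universe_size Annotation universe size (query included).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       herbs = c("HerbA", "HerbB"),
                       n_compounds = c(65, 116),
                       ob_range = c(0, 100), dl_range = c(0, 1),
                       ob_min = 30, dl_min = 0.18,
                       mapped_per_herb = c(6, 10),
                       targets_per_compound = 3,
                       herb_target_sizes = c(13, 41),
                       herb_overlap = 7,
                       gene_universe_size = 10000,
                       disease_gene_count = 7153,
                       planted_overlap = 44,
                       ppi_nodes = 40, ppi_attachment = 2,
                       planted_clique_size = 6,
                       n_terms = 50, term_size_range = c(10, 60),
                       planted_term_size = 40, planted_term_hits = 10,
                       query_size = 15,
                       annotation_universe_size = 2000) {
  cfg <- list(seed = as.integer(seed), herbs = herbs,
              n_compounds = n_compounds,
              ob_range = ob_range, dl_range = dl_range,
              ob_min = ob_min, dl_min = dl_min,
              mapped_per_herb = mapped_per_herb,
              targets_per_compound = targets_per_compound,
              herb_target_sizes = herb_target_sizes,
              herb_overlap = herb_overlap,
              gene_universe_size = gene_universe_size,
              disease_gene_count = disease_gene_count,
              planted_overlap = planted_overlap,
              ppi_nodes = ppi_nodes, ppi_attachment = ppi_attachment,
              planted_clique_size = planted_clique_size,
              n_terms = n_terms, term_size_range = term_size_range,
              planted_term_size = planted_term_size,
              planted_term_hits = planted_term_hits,
              query_size = query_size,
              annotation_universe_size = annotation_universe_size)
  stopifnot(length(cfg$herbs) == length(cfg$n_compounds),
            length(cfg$mapped_per_herb) == length(cfg$herbs),
            all(cfg$mapped_per_herb <= cfg$n_compounds),
            cfg$herb_overlap <= min(cfg$herb_target_sizes),
            sum(cfg$herb_target_sizes) - cfg$herb_overlap <=
              cfg$gene_universe_size,
            cfg$disease_gene_count <= cfg$gene_universe_size,
            cfg$planted_overlap <= cfg$disease_gene_count,
            cfg$planted_clique_size <= cfg$ppi_nodes,
            cfg$planted_term_hits <= min(cfg$planted_term_size,
                                         cfg$query_size),
            cfg$planted_term_size <= cfg$annotation_universe_size)
  structure(cfg, class = "sim_config")
}

sim_universe <- function(cfg) sprintf("G%05d", seq_len(cfg$gene_universe_size))

#' Generate a synthetic compound table
#'
#' Compounds per herb with OB and DL drawn uniformly from the configured
#' ranges, plus a manifest recording which records pass the ADME screen at
#' the configured thresholds. Reproducible under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `records` (a compound table as from
#'   [read_compound_table()]) and `manifest` (`data.frame` of `compound_id`,
#'   `passes`).
#' @export
gen_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- sum(cfg$n_compounds)
    records <- data.frame(
      compound_id = sprintf("SIM%04d", seq_len(n)),
      name = sprintf("compound_%d", seq_len(n)),
      ob = stats::runif(n, cfg$ob_range[1], cfg$ob_range[2]),
      dl = stats::runif(n, cfg$dl_range[1], cfg$dl_range[2]),
      herb = rep(cfg$herbs, cfg$n_compounds),
      manual_add = FALSE,
      stringsAsFactors = FALSE)
    manifest <- data.frame(
      compound_id = records$compound_id,
      passes = records$ob >= cfg$ob_min & records$dl >= cfg$dl_min,
      stringsAsFactors = FALSE)
    list(records = records, manifest = manifest)
  })
}

#' Generate a synthetic compound-target map and disease gene list
#'
#' Plants per-herb target pools of the configured sizes with the configured
#' herb-herb overlap, maps the configured number of compounds per herb to
#' zero-truncated-Poisson-sized subsets of their herb's pool (every pool
#' gene is covered by at least one compound; the remaining compounds map to
#' nothing, emulating database misses), and builds a disease gene collection
#' containing exactly `planted_overlap` of the drug targets plus random
#' filler genes. The manifest records all true sets.
#'
#' @param cfg A [sim_config()].
#' @param compounds Compound table from [gen_compound_table()] (the
#'   `records` element).
#' @return List with `map` (a [target_map()]), `disease` (a [gene_set()])
#'   and `manifest` (true per-herb target sets, herb overlap genes, drug
#'   union, planted drug-disease overlap, mapped compound ids, pair count).
#' @export
gen_target_map <- function(cfg, compounds) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    universe <- sim_universe(cfg)
    n_herbs <- length(cfg$herbs)
    shared <- sample(universe, cfg$herb_overlap)
    remaining <- setdiff(universe, shared)
    pools <- vector("list", n_herbs)
    for (i in seq_len(n_herbs)) {
      uniq_n <- cfg$herb_target_sizes[i] - cfg$herb_overlap
      uniq <- if (uniq_n > 0) sample(remaining, uniq_n) else character(0)
      remaining <- setdiff(remaining, uniq)
      pools[[i]] <- c(shared, uniq)
    }
    names(pools) <- cfg$herbs

    pairs_c <- character(0); pairs_g <- character(0)
    mapped_ids <- character(0)
    for (i in seq_len(n_herbs)) {
      sub <- compounds[compounds$herb == cfg$herbs[i], , drop = FALSE]
      manual <- if ("manual_add" %in% names(sub)) sub$manual_add else FALSE
      ids <- sub$compound_id[sub$ob >= cfg$ob_min & sub$dl >= cfg$dl_min &
                               !manual]
      m <- cfg$mapped_per_herb[i]
      if (m == 0) next
      if (m > length(ids)) {
        stop_format("herb '%s' has only %d screen-passing compounds but %d were requested for mapping",
                    cfg$herbs[i], length(ids), m)
      }
      mapped <- sample(ids, m)
      mapped_ids <- c(mapped_ids, mapped)
      pool <- pools[[i]]
      assigned <- lapply(mapped, function(id) {
        s <- max(1L, stats::rpois(1, cfg$targets_per_compound))
        sample(pool, min(s, length(pool)))
      })
      uncovered <- setdiff(pool, unlist(assigned))
      if (length(uncovered)) {
        slots <- sample(seq_len(m), length(uncovered), replace = TRUE)
        for (j in seq_along(uncovered)) {
          assigned[[slots[j]]] <- c(assigned[[slots[j]]], uncovered[j])
        }
      }
      pairs_c <- c(pairs_c, rep(mapped, lengths(assigned)))
      pairs_g <- c(pairs_g, unlist(assigned))
    }
    map <- target_map(pairs_c, pairs_g)

    drug_union <- sort(unique(unlist(pools[cfg$mapped_per_herb > 0])))
    if (cfg$planted_overlap > length(drug_union)) {
      stop_format("planted drug-disease overlap (%d) exceeds the drug target union (%d)",
                  cfg$planted_overlap, length(drug_union))
    }
    planted <- if (cfg$planted_overlap > 0) {
      sample(drug_union, cfg$planted_overlap)
    } else {
      character(0)
    }
    filler_pool <- setdiff(universe, drug_union)
    filler <- sample(filler_pool, cfg$disease_gene_count - length(planted))
    disease <- gene_set(c(planted, filler), label = "disease")

    manifest <- list(herb_targets = lapply(pools, sort),
                     herb_overlap_genes = sort(shared),
                     drug_targets = drug_union,
                     disease_overlap_genes = sort(planted),
                     mapped_compounds = sort(mapped_ids),
                     n_pairs = nrow(map))
    list(map = map, disease = disease, manifest = manifest)
  })
}

#' Generate a synthetic PPI graph with a planted clique
#'
#' A preferential-attachment backbone (heavy-tailed degree distribution;
#' `ppi_attachment = 1` yields a tree, hence a triangle-free graph) into
#' which one clique of the configured size is wired by adding all pairwise
#' edges among randomly chosen backbone nodes. The manifest records the
#' clique members.
#'
#' @param cfg A [sim_config()].
#' @param node_names Optional character vector of `ppi_nodes` node names
#'   (e.g. real gene symbols); defaults to `N001`, `N002`, ...
#' @return List with `graph` (a [ppi_graph()]) and `manifest`
#'   (`clique_members`, `n_nodes`, `n_edges`).
#' @export
gen_ppi <- function(cfg, node_names = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$ppi_nodes
  nm <- normalize_symbols(node_names %||% sprintf("N%03d", seq_len(n)))
  stopifnot(length(nm) == n, !anyDuplicated(nm))
  with_seed(cfg$seed + 2L, {
    backbone <- igraph::sample_pa(n, power = 1, m = cfg$ppi_attachment,
                                  directed = FALSE)
    el <- igraph::as_edgelist(backbone, names = FALSE)
    edges <- cbind(nm[el[, 1]], nm[el[, 2]])
    clique <- character(0)
    if (cfg$planted_clique_size >= 2) {
      clique <- sort(nm[sample(n, cfg$planted_clique_size)])
      extra <- t(utils::combn(clique, 2))
      edges <- rbind(edges, extra)
    }
    g <- ppi_graph(edges, nodes = nm)
    list(graph = g,
         manifest = list(clique_members = clique,
                         n_nodes = n_nodes(g), n_edges = n_edges(g)))
  })
}

#' Generate a synthetic annotation collection with one planted term
#'
#' Background terms draw their genes uniformly from a universe containing
#' the query; one planted term receives a stated number of query genes (its
#' remaining members come from outside the query). The manifest names the
#' planted term.
#'
#' @param cfg A [sim_config()].
#' @param query [gene_set()] or character vector; must fit inside the
#'   configured universe size.
#' @return List with `collection` (an [annotation_collection()]) and
#'   `manifest` (`planted_term`, `planted_hits`, `universe_size`).
#' @export
gen_annotations <- function(cfg, query) {
  stopifnot(inherits(cfg, "sim_config"))
  q <- as_gene_vector(query)
  stopifnot(length(q) >= cfg$planted_term_hits,
            length(q) <= cfg$annotation_universe_size)
  with_seed(cfg$seed + 3L, {
    n_bg <- cfg$annotation_universe_size - length(q)
    universe <- sort(c(q, sprintf("BG%05d", seq_len(n_bg))))
    ids <- sprintf("T%03d", seq_len(cfg$n_terms))
    planted_id <- ids[cfg$n_terms]
    terms <- vector("list", cfg$n_terms)
    names(terms) <- ids
    for (i in seq_len(cfg$n_terms - 1)) {
      size <- sample(cfg$term_size_range[1]:cfg$term_size_range[2], 1)
      terms[[i]] <- list(description = sprintf("background term %d", i),
                         genes = sort(sample(universe, size)))
    }
    hits <- sample(q, cfg$planted_term_hits)
    rest <- sample(setdiff(universe, q),
                   cfg$planted_term_size - cfg$planted_term_hits)
    terms[[cfg$n_terms]] <- list(description = "planted enriched term",
                                 genes = sort(c(hits, rest)))
    list(collection = annotation_collection(terms, universe),
         manifest = list(planted_term = planted_id,
                         planted_hits = cfg$planted_term_hits,
                         universe_size = length(universe)))
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Serializes a compound table, target map, disease gene list, PPI edge list
#' and GMT collection generated from one [sim_config()], plus a
#' `manifest.json` with the ground truth, so the pipeline can be exercised
#' end-to-end from files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects and manifests.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- gen_compound_table(cfg)
  tmap <- gen_target_map(cfg, comp$records)
  overlap <- tmap$manifest$disease_overlap_genes
  ppi <- gen_ppi(cfg, node_names = if (length(overlap) >= cfg$ppi_nodes) {
    sample_overlap <- with_seed(cfg$seed + 4L,
                                sample(overlap, cfg$ppi_nodes))
    sample_overlap
  } else {
    NULL
  })
  hubs_guess <- gene_set(overlap, label = "overlap")
  anno <- gen_annotations(cfg, hubs_guess)

  utils::write.table(
    data.frame(id = comp$records$compound_id, name = comp$records$name,
               ob = comp$records$ob, dl = comp$records$dl,
               source = comp$records$herb,
               manual_add = comp$records$manual_add),
    file.path(dir, "compounds.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tmap$map, file.path(dir, "target_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("compound_id", "gene_symbol"))
  writeLines(tmap$disease$genes, file.path(dir, "disease_genes.txt"))
  write_ppi_edgelist(ppi$graph, file.path(dir, "ppi_edges.tsv"))
  gmt_lines <- vapply(names(anno$collection$terms), function(id) {
    t <- anno$collection$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, file.path(dir, "annotations.gmt"))
  manifest <- list(compounds = comp$manifest, targets = tmap$manifest,
                   ppi = ppi$manifest, annotations = anno$manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(compounds = comp, targets = tmap, ppi = ppi,
                 annotations = anno))
}
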