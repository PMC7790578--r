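#' Pipeline configuration
#'
#' Collects the input paths and thresholds of a full network-pharmacology
#' run: ADME screen, per-herb target sets and herb-herb overlap, drug-disease
#' overlap, compound-target bipartite network, PPI ingest and cleanup,
#' centrality/median hub selection with MCC top-k ranking, and
#' over-representation analysis of the retained hubs.
#'
#' @param compound_table Path to a compound table
#'   ([read_compound_table()] format).
#' @param target_map Path to a compound-target TSV ([read_target_map()]).
#' @param disease_genes Path to a disease gene list ([read_gene_list()]).
#' @param ppi_edges Path to a STRING-style edge list
#'   ([read_ppi_edgelist()]).
#' @param gmt Path to a GMT annotation collection ([read_gmt()]).
#' @param out_dir Output directory for stage TSVs and the JSON run report.
#' @param ob_min,dl_min ADME thresholds (percent; dimensionless).
#' @param include_manual Pass `manual_add` compounds through the screen?
#' @param score_min PPI combined-score threshold (0-1000).
#' @param median_rule `"inclusive"` or `"strict"` consensus rule.
#' @param top_k Number of MCC-ranked core genes to report.
#' @param p_cut,q_cut ORA significance cutoffs.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given its input files).
#' @param stages Subset of
#'   `c("screen", "targets", "overlap", "network", "ppi", "hubs", "enrich")`
#'   to execute; later stages require the earlier ones.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(compound_table = NULL, target_map = NULL,
                            disease_genes = NULL, ppi_edges = NULL,
                            gmt = NULL, out_dir = tempfile("netpharm_run_"),
                            ob_min = 30, dl_min = 0.18,
                            include_manual = FALSE, score_min = 400,
                            median_rule = c("inclusive", "strict"),
                            top_k = 5, p_cut = 0.05, q_cut = 0.05,
                            seed = 1,
                            stages = c("screen", "targets", "overlap",
                                       "network", "ppi", "hubs", "enrich")) {
  median_rule <- match.arg(median_rule)
  all_stages <- c("screen", "targets", "overlap", "network", "ppi", "hubs",
                  "enrich")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stopifnot(ob_min >= 0, dl_min >= 0, score_min >= 0, score_min <= 1000,
            top_k >= 1, p_cut > 0, p_cut <= 1, q_cut > 0, q_cut <= 1)
  structure(list(compound_table = compound_table, target_map = target_map,
                 disease_genes = disease_genes, ppi_edges = ppi_edges,
                 gmt = gmt, out_dir = out_dir,
                 ob_min = ob_min, dl_min = dl_min,
                 include_manual = include_manual, score_min = score_min,
                 median_rule = median_rule, top_k = top_k,
                 p_cut = p_cut, q_cut = q_cut, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_format("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

require_input <- function(cfg, field, stage) {
  if (is.null(cfg[[field]])) {
    stop_format("stage '%s' requires the '%s' input", stage, field)
  }
  cfg[[field]]
}

#' Run the full inference pipeline
#'
#' Executes the configured stages in order, writes one TSV per stage plus a
#' versioned JSON run report (`run_report.json`) into `out_dir`, and returns
#' the report. The report carries every stage-level count (compounds
#' passing, per-herb target sizes, overlap sizes, network nodes/edges,
#' per-metric medians, retained hubs, top-k core genes, significant terms)
#' together with every threshold used, so each number is recomputable from
#' the stage outputs. Given identical inputs and configuration, the written
#' report is byte-identical across runs.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  report <- list(
    schema_version = "1.0",
    stages_run = cfg$stages,
    thresholds = list(ob_min = cfg$ob_min, dl_min = cfg$dl_min,
                      include_manual = cfg$include_manual,
                      score_min = cfg$score_min,
                      median_rule = cfg$median_rule, top_k = cfg$top_k,
                      p_cut = cfg$p_cut, q_cut = cfg$q_cut,
                      seed = cfg$seed))
  tsv <- function(x, name) {
    utils::write.table(x, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  active <- NULL
  if ("screen" %in% cfg$stages) {
    report$screen <- run_stage("screen", {
      tab <- read_compound_table(require_input(cfg, "compound_table",
                                               "screen"))
      screened <- adme_screen(tab, cfg$ob_min, cfg$dl_min,
                              cfg$include_manual)
      tsv(screened, "screened_compounds.tsv")
      active <- screened[screened$passed, , drop = FALSE]
      summ <- per_herb_summary(active)
      list(n_input = nrow(tab), n_pass = nrow(active),
           per_herb = stats::setNames(as.list(summ$n_compounds), summ$herb),
           top_ob = stats::setNames(
             lapply(seq_len(nrow(summ)), function(i)
               list(compound = summ$top_compound[i], ob = summ$top_ob[i])),
             summ$herb))
    })
  }

  map <- NULL; herb_sets <- NULL; drug <- NULL
  if ("targets" %in% cfg$stages) {
    report$targets <- run_stage("targets", {
      if (is.null(active)) stop("the 'screen' stage must run first")
      map <- read_target_map(require_input(cfg, "target_map", "targets"))
      herbs <- unique(active$herb)
      herb_sets <- lapply(herbs, function(h) {
        targets_of_herb(map, active[active$herb == h, , drop = FALSE])
      })
      names(herb_sets) <- herbs
      drug <- gene_set(unlist(lapply(herb_sets, `[[`, "genes")),
                        label = "drug")
      res <- list(per_herb = lapply(herb_sets,
                                    function(s) length(s$genes)),
                  n_union = length(drug$genes))
      if (length(herb_sets) == 2) {
        rep2 <- set_intersection_report(herb_sets[[1]], herb_sets[[2]])
        res$herb_overlap <- rep2$n_intersection
        writeLines(rep2$intersection,
                   file.path(cfg$out_dir, "herb_shared_targets.txt"))
      }
      writeLines(drug$genes, file.path(cfg$out_dir, "drug_targets.txt"))
      res
    })
  }

  overlap <- NULL
  if ("overlap" %in% cfg$stages) {
    report$overlap <- run_stage("overlap", {
      if (is.null(drug)) stop("the 'targets' stage must run first")
      disease <- read_gene_list(require_input(cfg, "disease_genes",
                                              "overlap"),
                                label = "disease")
      overlap <- drug_disease_overlap(drug, disease)
      rep2 <- set_intersection_report(drug, disease)
      writeLines(overlap$genes,
                 file.path(cfg$out_dir, "overlap_genes.txt"))
      list(n_drug = rep2$n_a, n_disease = rep2$n_b,
           n_overlap = rep2$n_intersection, n_union = rep2$n_union)
    })
  }

  if ("network" %in% cfg$stages) {
    report$network <- run_stage("network", {
      if (is.null(overlap)) stop("the 'overlap' stage must run first")
      net <- build_bipartite(map, active, overlap)
      write_sif(net, file.path(cfg$out_dir, "compound_target_network.sif"),
                file.path(cfg$out_dir, "compound_target_nodes.tsv"))
      list(n_compounds = length(net$compound_nodes),
           n_genes = length(net$gene_nodes),
           n_edges = nrow(net$edges))
    })
  }

  ppi <- NULL
  if ("ppi" %in% cfg$stages) {
    report$ppi <- run_stage("ppi", {
      if (is.null(overlap)) stop("the 'overlap' stage must run first")
      raw <- read_ppi_edgelist(require_input(cfg, "ppi_edges", "ppi"),
                               score_min = cfg$score_min)
      ppi <- remove_isolated_nodes(raw, keep = overlap)
      write_ppi_edgelist(ppi, file.path(cfg$out_dir, "ppi_clean.tsv"))
      tsv(degree_rank_report(ppi), "ppi_degree_rank.tsv")
      list(n_nodes_raw = n_nodes(raw), n_edges_raw = n_edges(raw),
           n_nodes = n_nodes(ppi), n_edges = n_edges(ppi))
    })
  }

  hubs <- NULL
  if ("hubs" %in% cfg$stages) {
    report$hubs <- run_stage("hubs", {
      if (is.null(ppi)) stop("the 'ppi' stage must run first")
      cent <- compute_all_centralities(ppi)
      tsv(cent, "centrality_table.tsv")
      sel <- median_filter(cent, rule = cfg$median_rule)
      ranking <- mcc(ppi)
      top <- top_k(ranking, min(cfg$top_k, nrow(ranking)))
      tsv(top, "core_genes.tsv")
      hubs <- gene_set(sel$retained, label = "hubs")
      writeLines(sel$retained, file.path(cfg$out_dir, "hub_genes.txt"))
      list(medians = as.list(sel$medians),
           n_retained = length(sel$retained), retained = sel$retained,
           core_genes = top$node)
    })
  }

  if ("enrich" %in% cfg$stages) {
    report$enrich <- run_stage("enrich", {
      if (is.null(hubs)) stop("the 'hubs' stage must run first")
      collection <- read_gmt(require_input(cfg, "gmt", "enrich"))
      res <- ora(hubs, collection, p_cut = cfg$p_cut, q_cut = cfg$q_cut)
      write_enrichment(res, file.path(cfg$out_dir, "enrichment.tsv"))
      list(n_terms_tested = length(collection$terms),
           n_reported = nrow(res),
           n_significant = sum(res$significant),
           top_terms = utils::head(res$term_id[res$significant], 10))
    })
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
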