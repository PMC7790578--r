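#' Construct a labelled gene set
#'
#' Gene identity throughout the package is the uppercased, whitespace-trimmed
#' HGNC-style symbol string; no alias resolution is attempted. Symbols are
#' de-duplicated and sorted.
#'
#' @param genes Character vector of gene symbols (or another `gene_set`).
#' @param label Short label for reports.
#' @return An object of class `gene_set` with fields `label` and `genes`.
#' @export
gene_set <- function(genes, label = "gene_set") {
  g <- normalize_symbols(unlist(genes, use.names = FALSE))
  g <- sort(unique(g[nzchar(g)]))
  structure(list(label = as.character(label)[1], genes = g),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$label, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene list file
#'
#' One symbol per line; `#` starts a comment (whole-line or trailing); blank
#' lines are ignored. Used for disease gene collections, which are accepted
#' verbatim — no score threshold is applied.
#'
#' @param path Path to a text file.
#' @param label Label for the resulting set; defaults to the file name.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stop_format("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  gene_set(lines[nzchar(trimws(lines))],
           label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Read a compound-to-target map
#'
#' Two-column tab-delimited file of (compound id, gene symbol) pairs — the
#' flat-file surrogate for a target-database lookup. Symbols are normalized
#' (uppercase, trimmed) and duplicate pairs collapse to one; the result has
#' set semantics. A header line whose first field is `compound_id` (or `id`)
#' is skipped.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `compound_id` and `gene`, class
#'   `target_map`.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop_format("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) &&
      tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1]) %in%
        c("compound_id", "id", "compound")) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(target_map(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop_format("target map parse error: expected 2 tab-separated fields at line %d",
                bad[1])
  }
  m <- do.call(rbind, fields)
  target_map(trimws(m[, 1]), m[, 2])
}

#' @rdname read_target_map
#' @param compound_id,gene Equal-length character vectors of pairs.
#' @export
target_map <- function(compound_id, gene) {
  df <- unique(data.frame(compound_id = as.character(compound_id),
                          gene = normalize_symbols(gene),
                          stringsAsFactors = FALSE))
  df <- df[nzchar(df$compound_id) & nzchar(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_map", "data.frame")
  df
}

#' Targets of one herb's compounds
#'
#' Union of the gene symbols mapped to any of the herb's compounds; compounds
#' absent from the map contribute nothing. All supplied compounds must carry
#' the same herb label.
#'
#' @param map A [target_map()].
#' @param compounds Compound table rows for a single herb.
#' @return A [gene_set()] labelled with the herb name.
#' @export
targets_of_herb <- function(map, compounds) {
  herb <- unique(compounds$herb)
  if (length(herb) > 1) {
    stop_format("targets_of_herb expects compounds of a single herb, got: %s",
                paste(herb, collapse = ", "))
  }
  gene_set(map$gene[map$compound_id %in% compounds$compound_id],
           label = if (length(herb)) herb else "herb")
}

#' Pairwise set overlap report
#'
#' Sizes of two gene sets, their intersection and union, plus the sorted
#' intersection list — the numeric content of a two-set Venn diagram. The
#' inclusion-exclusion identity `|a| + |b| = |union| + |intersection|` is
#' asserted on every report.
#'
#' @param a,b [gene_set()] objects.
#' @return An `overlap_report` list with fields `label_a`, `label_b`, `n_a`,
#'   `n_b`, `n_intersection`, `n_union`, `intersection`.
#' @export
set_intersection_report <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  inter <- sort(intersect(a$genes, b$genes))
  uni <- union(a$genes, b$genes)
  out <- structure(list(label_a = a$label, label_b = b$label,
                        n_a = length(a$genes), n_b = length(b$genes),
                        n_intersection = length(inter), n_union = length(uni),
                        intersection = inter),
                   class = "overlap_report")
  stopifnot(out$n_a + out$n_b == out$n_union + out$n_intersection)
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap: |%s| = %d, |%s| = %d, intersection %d, union %d>\n",
              x$label_a, x$n_a, x$label_b, x$n_b,
              x$n_intersection, x$n_union))
  if (x$n_intersection) {
    cat(" ", paste(x$intersection, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Intersection size from printed set sizes
#'
#' Inclusion-exclusion applied to reported counts: when only `|A|`, `|B|` and
#' `|A union B|` are published, the intersection size is
#' `|A| + |B| - |A union B|`. Useful for checking Venn counts against a
#' paper's printed set sizes.
#'
#' @param n_a,n_b,n_union Non-negative integer set sizes.
#' @return Integer intersection size.
#' @examples
#' intersection_from_counts(13, 41, 47)  # 7 shared targets
#' @export
intersection_from_counts <- function(n_a, n_b, n_union) {
  stopifnot(n_a >= 0, n_b >= 0, n_union >= 0)
  if (n_union > n_a + n_b || n_union < max(n_a, n_b)) {
    stop_format("inconsistent set sizes: |union| = %d outside [%d, %d]",
                n_union, max(n_a, n_b), n_a + n_b)
  }
  as.integer(n_a + n_b - n_union)
}

#' Drug-disease target overlap
#'
#' Genes shared between a drug (combined herb) target set and a disease gene
#' collection — the candidate therapeutic targets carried into network
#' construction.
#'
#' @param drug,disease [gene_set()] objects.
#' @return A [gene_set()] labelled `"overlap"`.
#' @export
drug_disease_overlap <- function(drug, disease) {
  stopifnot(inherits(drug, "gene_set"), inherits(disease, "gene_set"))
  gene_set(intersect(drug$genes, disease$genes), label = "overlap")
}
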