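#' Read a GMT annotation collection
#'
#' GMT lines are `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Lines with fewer than three fields and duplicated term ids are errors.
#' Unless an explicit `universe` is supplied, the background universe is the
#' union of all term genes; a supplied universe restricts every term to it
#' (genes outside the background cannot be drawn).
#'
#' @param path Path to the GMT file.
#' @param universe Optional [gene_set()] or character vector background.
#' @return An `annotation_collection`: list with `terms` (named list of
#'   `list(description, genes)`) and `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_format("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop_format("GMT parse error: fewer than 3 fields at line %d", bad[1])
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_format("GMT parse error: duplicate term id '%s'",
                ids[duplicated(ids)][1])
  }
  terms <- lapply(fields, function(f) {
    list(description = f[2],
         genes = sort(unique(normalize_symbols(f[-(1:2)]))))
  })
  names(terms) <- ids
  annotation_collection(terms, universe)
}

#' @rdname read_gmt
#' @param terms Named list of `list(description, genes)` entries.
#' @export
annotation_collection <- function(terms, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(terms, `[[`, "genes"),
                                   use.names = FALSE)))
  } else {
    universe <- as_gene_vector(universe)
    terms <- lapply(terms, function(t) {
      t$genes <- intersect(t$genes, universe)
      t
    })
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection: %d terms, universe of %d genes>\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` annotated genes in a query of size `n` drawn without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. Evaluated through the stable survival function rather than by
#' naive summation.
#'
#' @param k Observed overlap (integer, `0 <= k <= min(K, n)`).
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return Probability in `(0, 1]`.
#' @examples
#' hypergeom_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    stop_format("hypergeom_tail domain error: arguments must be integers")
  }
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stop_format("hypergeom_tail domain error: need 0 <= k <= min(K, n) and 0 <= K, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values:
#' `q_i = min over j >= rank(i) of m * p_(j) / j`, clipped at 1, returned in
#' the input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis
#'
#' Hypergeometric test of each annotation term against a query gene list,
#' with BH q-values. The effective query is the intersection of the supplied
#' genes with the collection's universe and must be non-empty. Terms with no
#' query hit (`k = 0`) are suppressed from the output; q-values are computed
#' across the reported terms. Rows are sorted by p ascending, ties by term
#' id, and flagged `significant` when `p <= p_cut` and `q <= q_cut`.
#'
#' @param query [gene_set()] or character vector of query genes.
#' @param collection An [annotation_collection()].
#' @param p_cut,q_cut Significance cutoffs. Defaults 0.05 and 0.05.
#' @return A `data.frame` (class `enrichment_result`) with columns
#'   `term_id`, `description`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
ora <- function(query, collection, p_cut = 0.05, q_cut = 0.05) {
  stopifnot(inherits(collection, "annotation_collection"))
  q <- intersect(as_gene_vector(query), collection$universe)
  if (!length(q)) {
    stop_format("ORA error: query has no genes in the annotation universe")
  }
  N <- length(collection$universe)
  n <- length(q)
  rows <- lapply(names(collection$terms), function(id) {
    term <- collection$terms[[id]]
    k <- sum(q %in% term$genes)
    if (k == 0) return(NULL)
    data.frame(term_id = id, description = term$description,
               k = k, K = length(term$genes), n = n, N = N,
               p = hypergeom_tail(k, length(term$genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  out$significant <- out$p <= p_cut & out$q <= q_cut
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment result as TSV
#'
#' @param result An [ora()] result.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
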