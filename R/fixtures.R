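#' Packaged reference fixtures
#'
#' Two small reference tables ship with the package as plain TSV:
#'
#' * `"table1"` — the 39-row two-herb compound screen (26 Fuzi + 13 Banxia
#'   candidates with OB/DL descriptors; the five literature re-added Fuzi
#'   alkaloids are flagged `manual_add`). Returned via
#'   [read_compound_table()].
#' * `"table2"` — the 13-row consensus-hub centrality table (degree,
#'   eigenvector, LAC, betweenness, closeness, network centrality per gene).
#'   Returned with metric columns renamed to the package's `dc`, `ec`,
#'   `lac`, `bc`, `cc`, `nc` schema, and with the published per-metric
#'   medians of the full 39-node network attached as
#'   `attr(x, "reference_medians")` (those medians were computed over all
#'   39 network nodes, not just the 13 retained rows, so they are metadata
#'   here rather than recomputable from the table).
#'
#' @param name `"table1"` or `"table2"`.
#' @return A `data.frame`; see Details.
#' @examples
#' nrow(load_fixture("table1"))  # 39
#' attr(load_fixture("table2"), "reference_medians")
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("table1", "table2")) {
    stop_format("unknown fixture '%s'; available: 'table1', 'table2'",
                as.character(name)[1])
  }
  if (name == "table1") {
    return(read_compound_table(
      system.file("extdata", "fuzi_banxia_table1.tsv",
                  package = "netpharm", mustWork = TRUE)))
  }
  raw <- utils::read.delim(
    system.file("extdata", "hub_centrality_table2.tsv",
                package = "netpharm", mustWork = TRUE),
    stringsAsFactors = FALSE)
  out <- data.frame(node = raw$node,
                    dc = raw$degree, bc = raw$betweenness,
                    cc = raw$closeness, ec = raw$eigenvector,
                    lac = raw$lac, nc = raw$network,
                    stringsAsFactors = FALSE)
  attr(out, "reference_medians") <- c(dc = 8, bc = 16.4307, cc = 0.5067,
                                      ec = 0.1181, lac = 3.75, nc = 6.1431)
  class(out) <- c("centrality_table", "data.frame")
  out
}
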