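#' Read a herb compound table
#'
#' Reads a TCMSP-style export of candidate herb compounds with their oral
#' bioavailability (OB, percent) and drug-likeness (DL, dimensionless)
#' descriptors. The header must name the five fields `id`, `name`, `ob`, `dl`,
#' `source` (case-insensitive; `compound_id` and `herb` are accepted synonyms
#' for `id` and `source`). An optional logical `manual_add` column flags
#' compounds that were added to the study by hand rather than by the ADME
#' screen; absent, it defaults to `FALSE`.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. Default `NULL` auto-detects from the file
#'   extension: `","` for `.csv`, otherwise tab.
#' @return A `data.frame` with columns `compound_id`, `name`, `ob`, `dl`,
#'   `herb`, `manual_add`, one row per input row, input order preserved.
#' @examples
#' tab <- read_compound_table(
#'   system.file("extdata", "fuzi_banxia_table1.tsv", package = "netpharm"))
#' nrow(tab)
#' @seealso [adme_filter()], [per_herb_summary()]
#' @export
read_compound_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_format("file not found: '%s'", path)
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  }
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "")
  names(raw) <- tolower(trimws(names(raw)))
  names(raw)[names(raw) == "compound_id"] <- "id"
  names(raw)[names(raw) == "herb"] <- "source"

  required <- c("id", "name", "ob", "dl", "source")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_format("compound table format error: missing column(s) %s",
                paste(sQuote(missing), collapse = ", "))
  }

  parse_num <- function(col) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & nzchar(raw[[col]]))
    if (length(bad) == 0) bad <- which(is.na(val))
    if (length(bad)) {
      stop_format("compound table parse error: non-numeric %s value '%s' at data row %d",
                  toupper(col), raw[[col]][bad[1]], bad[1])
    }
    val
  }
  ob <- parse_num("ob")
  dl <- parse_num("dl")
  if (any(ob < 0) || any(dl < 0)) {
    stop_format("compound table invariant violated: OB and DL must be non-negative")
  }

  manual <- if ("manual_add" %in% names(raw)) {
    toupper(trimws(raw$manual_add)) %in% c("TRUE", "T", "1", "YES")
  } else {
    rep(FALSE, nrow(raw))
  }

  out <- data.frame(compound_id = trimws(raw$id),
                    name = trimws(raw$name),
                    ob = ob, dl = dl,
                    herb = trimws(raw$source),
                    manual_add = manual,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$compound_id))) {
    stop_format("compound table invariant violated: empty compound id")
  }
  # same molecule may occur in two herbs; uniqueness holds within a herb
  dup <- duplicated(out[, c("compound_id", "herb")])
  if (any(dup)) {
    stop_format("compound table invariant violated: duplicate compound id '%s' within herb '%s'",
                out$compound_id[dup][1], out$herb[dup][1])
  }
  out
}

#' Screen compounds by oral bioavailability and drug-likeness
#'
#' `adme_screen()` annotates each record with a logical `passed` column;
#' `adme_filter()` returns only the passing records. A record passes when
#' `ob >= ob_min` **and** `dl >= dl_min`, both comparisons inclusive, so a
#' compound sitting exactly on the drug-likeness boundary is retained.
#' Records flagged `manual_add` are handled outside the numeric screen: they
#' are excluded unless `include_manual = TRUE`, in which case they pass
#' unconditionally (they represent compounds re-added on literature grounds).
#'
#' @param records Compound table from [read_compound_table()].
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness. Default 0.18.
#' @param include_manual Keep `manual_add` records regardless of thresholds?
#' @return `adme_filter()`: the passing subset, input order preserved.
#'   `adme_screen()`: all records plus a `passed` column.
#' @examples
#' tab <- read_compound_table(
#'   system.file("extdata", "fuzi_banxia_table1.tsv", package = "netpharm"))
#' nrow(adme_filter(tab))  # 34 active compounds
#' @export
adme_filter <- function(records, ob_min = 30, dl_min = 0.18,
                        include_manual = FALSE) {
  screened <- adme_screen(records, ob_min, dl_min, include_manual)
  out <- screened[screened$passed, setdiff(names(screened), "passed"),
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname adme_filter
#' @export
adme_screen <- function(records, ob_min = 30, dl_min = 0.18,
                        include_manual = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("ob", "dl") %in% names(records)),
            is.finite(ob_min), is.finite(dl_min))
  manual <- if ("manual_add" %in% names(records)) records$manual_add
            else rep(FALSE, nrow(records))
  passed <- records$ob >= ob_min & records$dl >= dl_min
  passed[manual] <- include_manual
  records$passed <- passed
  records
}

#' Summarise screened compounds per herb
#'
#' For each source herb, reports the number of compounds and the compound with
#' the highest oral bioavailability (ties broken by first occurrence).
#'
#' @param records Non-empty compound table.
#' @return A `data.frame` with columns `herb`, `n_compounds`, `top_compound`,
#'   `top_ob`, in order of first appearance of each herb.
#' @examples
#' tab <- adme_filter(read_compound_table(
#'   system.file("extdata", "fuzi_banxia_table1.tsv", package = "netpharm")))
#' per_herb_summary(tab)
#' @export
per_herb_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  herbs <- unique(records$herb)
  rows <- lapply(herbs, function(h) {
    sub <- records[records$herb == h, , drop = FALSE]
    best <- which.max(sub$ob)  # first occurrence on ties
    data.frame(herb = h, n_compounds = nrow(sub),
               top_compound = sub$name[best], top_ob = sub$ob[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
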