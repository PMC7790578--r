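`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Gene identity throughout the package: uppercased, whitespace-trimmed symbol.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else sort(unique(normalize_symbols(x)))
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
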