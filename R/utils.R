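# Internal helpers shared across modules.

# Run `expr` with a private RNG state seeded by `seed`; NULL leaves the
# caller's RNG stream untouched and in use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_bb <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "betabrowning_error")))
}

check_count_matrix <- function(counts, arg = "counts") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop_bb("%s must be a numeric matrix", arg, class = "invalid_counts")
  }
  if (any(counts < 0)) {
    stop_bb("%s contains negative cells", arg, class = "invalid_counts")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  }
  counts
}

# largest-remainder rounding: integer vector summing to n, proportional to p
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}
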