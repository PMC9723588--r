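#' Configuration for MINE statistics
#'
#' @param alpha_exponent grid budget exponent: grids are limited to
#'   `cols * rows <= floor(n^alpha_exponent)` (default 0.6, the MINE
#'   default).
#' @param clump_factor clump budget `c`: the optimised axis is pre-grouped
#'   into at most `c * max_columns` superclumps (default 15).
#' @param n_perm permutations for the p-value (default 999).
#' @param mic_cutoff minimum MIC for a relationship to count (default 0.3).
#' @param mas_monotone_cutoff MAS strictly below this is called monotone
#'   (default 0.05).
#' @param fdr_level q-value significance level (default 0.05).
#' @param fdr_method `"BH"` (Benjamini-Hochberg step-up, the default) or
#'   `"hochberg"` (the family-wise Hochberg step-up, available behind this
#'   flag because the source of the cutoffs is ambiguous about which is
#'   meant).
#' @param seed integer seed for the permutation null.
#' @return a `mine_config` list.
#' @export
mine_config <- function(alpha_exponent = 0.6, clump_factor = 15,
                        n_perm = 999, mic_cutoff = 0.3,
                        mas_monotone_cutoff = 0.05, fdr_level = 0.05,
                        fdr_method = c("BH", "hochberg"), seed = NULL) {
  fdr_method <- match.arg(fdr_method)
  if (alpha_exponent <= 0 || alpha_exponent >= 1) {
    stop_bb("alpha_exponent must be in (0, 1)", class = "invalid_config")
  }
  if (clump_factor < 1) {
    stop_bb("clump_factor must be >= 1", class = "invalid_config")
  }
  if (n_perm < 99) stop_bb("n_perm must be >= 99", class = "invalid_config")
  structure(list(alpha_exponent = alpha_exponent,
                 clump_factor = clump_factor, n_perm = as.integer(n_perm),
                 mic_cutoff = mic_cutoff,
                 mas_monotone_cutoff = mas_monotone_cutoff,
                 fdr_level = fdr_level, fdr_method = fdr_method,
                 seed = seed),
            class = "mine_config")
}

grid_budget <- function(n, alpha_exponent) {
  max(4L, as.integer(floor(n^alpha_exponent)))
}

check_xy <- function(x, y, min_n = 10) {
  if (length(x) != length(y)) {
    stop_bb("x and y lengths differ", class = "invalid_input")
  }
  if (length(x) < min_n) {
    stop_bb("need at least %d points", min_n, class = "invalid_input")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_bb("constant variable: MINE statistics undefined",
            class = "degenerate_variable")
  }
  invisible(NULL)
}

#' Optimal clump-respecting column partitions (ApproxMaxMI dynamic program)
#'
#' With the row partition fixed, returns for every column count
#' `l = 2..max_columns` the maximum mutual information (bits) over
#' x-partitions into `l` columns whose boundaries respect the clump
#' structure of x. The result is nondecreasing in `l` and, restricted to
#' clump boundaries, exact.
#'
#' @param x the variable whose axis is optimised.
#' @param y_partition per-point row assignment (integer, >= 2 distinct
#'   rows).
#' @param max_columns largest column count to evaluate.
#' @param clump_factor superclump budget multiplier (see [mine_config()]).
#' @return numeric vector of mutual informations, names `"2"`..
#' @export
optimize_x_axis <- function(x, y_partition, max_columns, clump_factor = 15) {
  if (length(x) < 4) stop_bb("need n >= 4", class = "invalid_input")
  y_partition <- as.integer(factor(y_partition))
  if (length(unique(y_partition)) < 2) {
    stop_bb("fixed y partition must have >= 2 rows",
            class = "invalid_partition")
  }
  if (max_columns < 2) {
    stop_bb("max_columns must be >= 2", class = "invalid_partition")
  }
  out <- .optimize_x_axis_cpp(as.numeric(x), y_partition,
                              as.integer(max_columns),
                              as.numeric(clump_factor))
  names(out) <- as.character(2:max_columns)
  out
}

#' MINE characteristic matrix
#'
#' Normalised optimal grid mutual informations
#' `M[a, b] = I*(a x-bins, b y-bins) / log2(min(a, b))` for every grid shape
#' with `a * b <= floor(n^alpha_exponent)` and `a, b >= 2`. `I*` is
#' approximated by the better of the two heuristic orientations
#' (equipartition one axis, optimise the other by the clump dynamic
#' program).
#'
#' @param x,y numeric vectors of equal length (n >= 10), neither constant.
#' @param config a [mine_config()].
#' @return matrix with rows/columns named by bin counts (`NA` where the
#'   grid budget is exceeded); attribute `"budget"` carries B(n).
#' @export
characteristic_matrix <- function(x, y, config = mine_config()) {
  check_xy(x, y)
  B <- grid_budget(length(x), config$alpha_exponent)
  M <- .char_matrix_cpp(as.numeric(x), as.numeric(y), B,
                        config$clump_factor)
  dimnames(M) <- list(as.character(2:(nrow(M) + 1)),
                      as.character(2:(ncol(M) + 1)))
  attr(M, "budget") <- B
  M
}

#' MIC and MAS
#'
#' The maximal information coefficient is the largest entry of the
#' characteristic matrix; the maximum asymmetry score is the largest
#' absolute difference between an entry and its transpose,
#' `MAS = max |M[a, b] - M[b, a]|`, and measures deviation from
#' monotonicity.
#'
#' @inheritParams characteristic_matrix
#' @return named numeric vector `c(mic = ..., mas = ...)`, both in
#'   `[0, 1]`.
#' @export
mic_mas <- function(x, y, config = mine_config()) {
  check_xy(x, y)
  B <- grid_budget(length(x), config$alpha_exponent)
  v <- .mic_mas_cpp(as.numeric(x), as.numeric(y), B, config$clump_factor)
  c(mic = v[1], mas = v[2])
}

#' Permutation p-value for the MIC
#'
#' Permutes one variable `n_perm` times and applies the add-one convention
#' `p = (1 + #[MIC_perm >= MIC_obs]) / (n_perm + 1)`, so p is exact-level
#' by construction and always in (0, 1].
#'
#' @inheritParams characteristic_matrix
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `mic`, `p` and `n_perm`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 999, seed = NULL,
                               config = mine_config()) {
  check_xy(x, y)
  if (n_perm < 99) stop_bb("n_perm must be >= 99", class = "invalid_config")
  B <- grid_budget(length(x), config$alpha_exponent)
  v <- with_seed(seed, .mic_perm_cpp(as.numeric(x), as.numeric(y), B,
                                     config$clump_factor,
                                     as.integer(n_perm)))
  list(mic = v[1], p = (1 + v[2]) / (n_perm + 1), n_perm = n_perm)
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values `q_(i) = min_(j >= i) m p_(j) / j`,
#' capped at 1 (delegated to [stats::p.adjust()]); `method = "hochberg"`
#' applies the family-wise Hochberg step-up instead.
#'
#' @param p p-values in (0, 1].
#' @param method `"BH"` or `"hochberg"`.
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_bb("p-values must lie in (0, 1]", class = "invalid_p")
  }
  p.adjust(p, method = method)
}

#' Screen taxa for (non)monotonic gradient relationships
#'
#' For every taxon, computes MIC and MAS of its relative abundance against
#' the gradient, a seeded permutation p-value, FDR q-values across taxa,
#' and the Spearman correlation sign. Taxa with `q < fdr_level` and
#' `MIC >= mic_cutoff` are classified `"monotone"` when
#' `MAS < mas_monotone_cutoff` (strictly) and `"nonmonotone"` otherwise;
#' everything else is `"not_significant"`. All-zero taxa are skipped with a
#' warning and reported as not significant.
#'
#' @param counts site-by-taxon counts (converted to relative abundances so
#'   sequencing depth does not leak into the screen) or an
#'   already-relative abundance matrix.
#' @param gradient per-site browning values.
#' @param normalize divide each row by its sum before screening (default
#'   `TRUE`); set to `FALSE` when the input is already depth-free, e.g.
#'   noiseless expected abundances from a simulation.
#' @param config a [mine_config()]; its `seed` drives the permutation
#'   streams.
#' @return data.frame of class `mine_result` with columns `taxon`, `mic`,
#'   `mas`, `spearman_sign`, `p`, `q`, `class`.
#' @export
mine_screen <- function(counts, gradient, config = mine_config(),
                        normalize = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(gradient)) {
    stop_bb("gradient length must equal the number of sites",
            class = "invalid_input")
  }
  rel <- if (normalize) {
    rs <- rowSums(counts)
    counts / ifelse(rs > 0, rs, 1)
  } else counts
  n_taxa <- ncol(rel)
  out <- data.frame(taxon = colnames(rel), mic = NA_real_, mas = NA_real_,
                    spearman_sign = NA_real_, p = NA_real_, q = NA_real_,
                    class = "not_significant", stringsAsFactors = FALSE)
  seeds <- if (is.null(config$seed)) {
    rep(list(NULL), n_taxa)
  } else {
    as.list(config$seed * 131 + seq_len(n_taxa))
  }
  skipped <- character(0)
  for (j in seq_len(n_taxa)) {
    y <- rel[, j]
    if (all(y == 0) || length(unique(y)) < 2) {
      skipped <- c(skipped, out$taxon[j])
      next
    }
    pv <- permutation_pvalue(gradient, y, config$n_perm, seeds[[j]], config)
    mm <- mic_mas(gradient, y, config)
    out$mic[j] <- mm["mic"]
    out$mas[j] <- mm["mas"]
    out$p[j] <- pv$p
    out$spearman_sign[j] <- sign(cor(gradient, y, method = "spearman"))
  }
  if (length(skipped)) {
    warning(sprintf("%d all-zero/constant taxa skipped (reported as %s)",
                    length(skipped), "not_significant"))
  }
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok], config$fdr_method)
  sig <- ok & out$q < config$fdr_level & out$mic >= config$mic_cutoff
  out$class[sig] <- ifelse(out$mas[sig] < config$mas_monotone_cutoff,
                           "monotone", "nonmonotone")
  structure(out, class = c("mine_result", "data.frame"))
}

#' @export
print.mine_result <- function(x, ...) {
  tab <- table(factor(x$class,
                      c("monotone", "nonmonotone", "not_significant")))
  cat("MINE screen of", nrow(x), "taxa:\n")
  cat(sprintf("  monotone %d | nonmonotone %d | not significant %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}
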