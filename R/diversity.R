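#' Hellinger transformation
#'
#' Square roots of the per-site relative abundances:
#' `sqrt(count / row sum)`. Each transformed row has unit sum of squares,
#' which makes Euclidean-based ordination distance-appropriate for
#' community data.
#'
#' @param counts nonnegative site-by-taxon matrix.
#' @return numeric matrix of the same shape.
#' @examples
#' hellinger_transform(rbind(a = c(1, 1, 2)))
#' @export
hellinger_transform <- function(counts) {
  counts <- check_count_matrix(counts)
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    stop_bb("site '%s' has zero total count", rownames(counts)[rs <= 0][1],
            class = "zero_row")
  }
  sqrt(counts / rs)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_k - y_k| / sum (x_k + y_k)` for every site pair
#' (computed through [vegan::vegdist()]).
#'
#' @param x nonnegative site-by-variable matrix (counts or transformed
#'   abundances).
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    stop_bb("Bray-Curtis requires nonnegative entries",
            class = "invalid_counts")
  }
  rs <- rowSums(x)
  if (any(rs == 0) && sum(rs == 0) >= 1 && nrow(x) > 1) {
    zero <- which(rs == 0)
    # distance between two all-zero rows is 0/0
    if (length(zero) > 1) {
      stop_bb("distance undefined: sites %s are all zero",
              paste(rownames(x)[zero], collapse = ", "),
              class = "undefined_distance")
    }
  }
  as.matrix(vegan::vegdist(x, method = "bray"))
}

shannon_index <- function(p, base = exp(1)) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Fisher's alpha
#'
#' Solves `S = alpha * log(1 + N / alpha)` for alpha by root finding, where
#' `S` is the observed richness and `N` the total count of a site.
#'
#' @param counts_row counts for one site.
#' @return Fisher's alpha (scalar).
#' @export
fisher_alpha <- function(counts_row) {
  counts_row <- counts_row[counts_row > 0]
  S <- length(counts_row)
  N <- sum(counts_row)
  if (S <= 1 || S >= N) {
    stop_bb("Fisher's alpha has no solution for S = %d, N = %d", S, N,
            class = "no_solution")
  }
  f <- function(a) a * log1p(N / a) - S
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}

#' ACE richness estimator (Chao-Lee)
#'
#' `ACE = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2`, with sample
#' coverage `C_ace = 1 - F1 / N_rare` and the squared coefficient of
#' variation `gamma2` floored at zero. Taxa with count `<= rare_cutoff`
#' count as rare.
#'
#' @param counts_row counts for one site.
#' @param rare_cutoff rare/abundant boundary (default 10, the standard
#'   Chao-Lee choice).
#' @return list with `ace` and the components `S_abund`, `S_rare`, `F1`,
#'   `N_rare`, `C_ace`, `gamma2`.
#' @export
ace_richness <- function(counts_row, rare_cutoff = 10) {
  counts_row <- counts_row[counts_row > 0]
  if (!length(counts_row)) {
    stop_bb("empty count row", class = "estimator_undefined")
  }
  rare <- counts_row[counts_row <= rare_cutoff]
  S_abund <- sum(counts_row > rare_cutoff)
  S_rare <- length(rare)
  if (S_rare == 0) {
    return(list(ace = S_abund, S_abund = S_abund, S_rare = 0, F1 = 0,
                N_rare = 0, C_ace = 1, gamma2 = 0))
  }
  F1 <- sum(rare == 1)
  N_rare <- sum(rare)
  C_ace <- 1 - F1 / N_rare
  if (C_ace == 0) {
    stop_bb(paste0("ACE undefined: all rare taxa are singletons ",
                   "(coverage estimate 0); no silent fallback is applied"),
            class = "estimator_undefined")
  }
  Fi <- tabulate(rare, nbins = rare_cutoff)
  i <- seq_len(rare_cutoff)
  g2 <- (S_rare / C_ace) * sum(i * (i - 1) * Fi) /
    (N_rare * (N_rare - 1)) - 1
  gamma2 <- max(g2, 0)
  list(ace = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2,
       S_abund = S_abund, S_rare = S_rare, F1 = F1, N_rare = N_rare,
       C_ace = C_ace, gamma2 = gamma2)
}

#' Per-site alpha-diversity indices
#'
#' Computes the requested indices for every site: observed richness,
#' Shannon entropy `-sum p log p` (natural log by default, the convention
#' of the ecology toolchain, configurable via `shannon_base`), Simpson
#' concentration-complement `1 - sum p^2`, inverse Simpson `1 / sum p^2`
#' (both Simpson variants are reported to disambiguate "Simpson
#' diversity"), Fisher's alpha, and ACE. Shannon and Simpson are delegated
#' to [vegan::diversity()].
#'
#' @param counts site-by-taxon count matrix.
#' @param indices subset of `c("richness", "shannon", "simpson",
#'   "inv_simpson", "fisher", "ace")`.
#' @param shannon_base logarithm base for Shannon entropy.
#' @return data.frame with one row per site and one column per index.
#' @export
alpha_diversity <- function(counts,
                            indices = c("richness", "shannon", "simpson",
                                        "inv_simpson"),
                            shannon_base = exp(1)) {
  counts <- check_count_matrix(counts)
  indices <- match.arg(indices,
                       c("richness", "shannon", "simpson", "inv_simpson",
                         "fisher", "ace"), several.ok = TRUE)
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    stop_bb("site '%s' has zero total count", rownames(counts)[rs <= 0][1],
            class = "zero_row")
  }
  out <- data.frame(row.names = rownames(counts))
  for (ix in indices) {
    out[[ix]] <- switch(ix,
      richness = rowSums(counts > 0),
      shannon = vegan::diversity(counts, index = "shannon") /
        log(shannon_base),
      simpson = vegan::diversity(counts, index = "simpson"),
      inv_simpson = vegan::diversity(counts, index = "invsimpson"),
      fisher = apply(counts, 1, fisher_alpha),
      ace = apply(counts, 1, function(r) ace_richness(r)$ace))
  }
  out
}

#' Expected richness under rarefaction
#'
#' Expected number of taxa in a random subsample of `depth` reads drawn
#' without replacement: `E[S_n] = sum_k (1 - C(N - N_k, n) / C(N, n))`,
#' evaluated with log-binomial arithmetic (via [vegan::rarefy()]) so depths
#' in the 10^5 range do not overflow.
#'
#' @param counts_row counts for one site.
#' @param depth subsample size `n`, `1 <= n <= N`.
#' @return expected richness (scalar).
#' @export
rarefy_expected <- function(counts_row, depth) {
  N <- sum(counts_row)
  if (depth < 1 || depth > N) {
    stop_bb("depth %g outside [1, %d]", depth, N, class = "invalid_depth")
  }
  as.numeric(suppressWarnings(
    vegan::rarefy(matrix(counts_row, nrow = 1), sample = depth)))
}

#' Rarefy a count matrix by random subsampling
#'
#' Draws `depth` reads per site without replacement. When `depth` is
#' omitted it defaults to the minimum row sum — the common-depth rule of
#' rarefying to the sample with the fewest reads.
#'
#' @param counts site-by-taxon count matrix.
#' @param depth target reads per site (`<=` every row sum).
#' @param seed optional integer seed.
#' @return integer matrix; every row sums to `depth`, no cell exceeds its
#'   original count.
#' @export
rarefy_subsample <- function(counts, depth = NULL, seed = NULL) {
  counts <- check_count_matrix(counts)
  rs <- rowSums(counts)
  if (is.null(depth)) depth <- min(rs)
  if (any(rs < depth)) {
    stop_bb("depth %g exceeds the total count of site '%s'", depth,
            rownames(counts)[rs < depth][1], class = "invalid_depth")
  }
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(counts, sample = depth)))
  storage.mode(out) <- "integer"
  out
}

#' Exact (analytical) species accumulation curve
#'
#' Expected pooled richness when `m` of the `T` sites are drawn at random
#' without replacement: `E[S(m)] = sum_k (1 - C(T - T_k, m) / C(T, m))`
#' with `T_k` the number of sites occupied by taxon k (computed through
#' [vegan::specaccum()] with `method = "exact"`).
#'
#' @param counts site-by-taxon count matrix.
#' @return data.frame of class `accumulation_curve` with columns `m` and
#'   `richness`; nondecreasing, ending at the pooled richness.
#' @export
species_accum_exact <- function(counts) {
  counts <- check_count_matrix(counts)
  sac <- suppressWarnings(vegan::specaccum(counts, method = "exact"))
  structure(data.frame(m = sac$sites, richness = sac$richness),
            class = c("accumulation_curve", "data.frame"))
}

#' PCA browning index of absorption spectra
#'
#' Principal component analysis of the per-site absorption spectra
#' (columns standardised when `scale = TRUE`). PC1 is sign-oriented so its
#' scores correlate positively with mean absorbance, giving a reproducible
#' browning index direction.
#'
#' @param spectra site-by-wavelength matrix.
#' @param scale standardise wavelength columns first.
#' @param n_components number of components to return scores for.
#' @return list of class `pca_index` with `scores` (zero-mean columns
#'   `PC1`..), `variance_fraction` per returned component, and
#'   `pc1_percent` for convenience.
#' @export
cdom_pca_index <- function(spectra, scale = TRUE, n_components = 6) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2 || ncol(spectra) < 2) {
    stop_bb("need >= 2 sites and >= 2 wavelengths", class = "invalid_spectra")
  }
  if (scale && any(apply(spectra, 2, sd) == 0)) {
    stop_bb("constant wavelength column cannot be scaled",
            class = "degenerate_column")
  }
  pc <- prcomp(spectra, center = TRUE, scale. = scale)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (cor(scores[, 1], rowMeans(spectra)) < 0) {
    scores[, 1] <- -scores[, 1]
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, variance_fraction = vf[seq_len(k)],
                 pc1_percent = 100 * vf[1]),
            class = "pca_index")
}

#' @export
print.pca_index <- function(x, ...) {
  cat(sprintf("CDOM PCA index: PC1 explains %.1f%% of the variance (%d sites)\n",
              x$pc1_percent, nrow(x$scores)))
  invisible(x)
}
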