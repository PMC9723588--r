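# Monotonic comparators: RDA R^2, variance partitioning, distance decay,
# and the linear-vs-quadratic alpha-diversity hump test.

# Multivariate regression R^2 of centred Y on scaled X; rank-deficient X is
# either an error (naming the dependent columns) or fitted through the
# pivoting QR with the effective rank used for the adjustment.
rda_core <- function(Y, X, allow_rank_deficient = FALSE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop_bb("Y and X row counts differ",
                            class = "shape_error")
  Xs <- scale(X)
  Xs[, apply(X, 2, sd) == 0] <- 0
  qrX <- qr(Xs)
  p <- qrX$rank
  if (!allow_rank_deficient && p < ncol(Xs)) {
    dep <- colnames(X)[qrX$pivot[(p + 1):ncol(Xs)]]
    stop_bb("collinear predictors: %s", paste(dep, collapse = ", "),
            class = "collinearity_error")
  }
  if (n <= p + 1) {
    stop_bb("need n > p + 1 (n = %d, rank = %d)", n, p,
            class = "invalid_input")
  }
  Yc <- scale(Y, scale = FALSE)
  fit <- qr.fitted(qrX, Yc)
  r2 <- sum(fit^2) / sum(Yc^2)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), n = n, p = p)
}

#' Redundancy-analysis R-squared
#'
#' Fraction of total community variance (sum of squares of the centred
#' response matrix, typically Hellinger-transformed abundances) explained
#' by a linear fit on the scaled predictors, with the Ezekiel adjustment
#' `adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param Y site-by-taxon response matrix (e.g. [hellinger_transform()]
#'   output).
#' @param X per-site predictor table; scaled internally.
#' @return list of class `rda_fit`: `r2`, `adj_r2`, `n`, `p`.
#' @export
rda_r2 <- function(Y, X) {
  out <- rda_core(Y, X, allow_rank_deficient = FALSE)
  structure(out, class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: R^2 = %.4f, adjusted R^2 = %.4f (n = %d, p = %d)\n",
              x$r2, x$adj_r2, x$n, x$p))
  invisible(x)
}

#' Variance partitioning across predictor sets
#'
#' Decomposes the community variance explained by two or three named
#' predictor sets into unique and shared fractions by inclusion-exclusion
#' over the (adjusted, by default) R-squared of every nonempty subset
#' union — the varpart construction. Adjusted fractions may be negative
#' and are reported as such, not clipped. All fractions plus the residual
#' sum to 1 exactly (up to floating error).
#'
#' @param Y response matrix.
#' @param X_sets named list of 2 or 3 predictor tables.
#' @param adjusted use adjusted R-squared for the fractions (default
#'   `TRUE`, matching varpart); `FALSE` gives the raw-R2 decomposition,
#'   exact to machine precision.
#' @return list of class `variance_partition`: `fractions` (named vector;
#'   unique fractions keyed by set name, shared by `"a&b"`), `residual`,
#'   and the subset R2 table `subsets`.
#' @export
variance_partition <- function(Y, X_sets, adjusted = TRUE) {
  k <- length(X_sets)
  if (k < 2 || k > 3) stop_bb("X_sets must contain 2 or 3 sets",
                              class = "invalid_input")
  if (is.null(names(X_sets))) names(X_sets) <- letters[seq_len(k)]
  if (any(vapply(X_sets, function(x) ncol(as.matrix(x)) == 0, logical(1)))) {
    stop_bb("every predictor set must be nonempty", class = "invalid_input")
  }
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  U <- vapply(subsets, function(s) {
    X <- do.call(cbind, lapply(X_sets[s], as.matrix))
    fit <- rda_core(Y, X, allow_rank_deficient = TRUE)
    if (adjusted) fit$adj_r2 else fit$r2
  }, numeric(1))
  names(U) <- vapply(subsets, function(s) paste(names(X_sets)[s], collapse = "&"),
                     character(1))
  # intersection measures by inclusion-exclusion over union R2 values
  imeas <- function(s) {
    tt <- subsets[vapply(subsets, function(t) all(t %in% s), logical(1))]
    sum(vapply(tt, function(t) (-1)^(length(t) + 1) *
                 U[[paste(names(X_sets)[t], collapse = "&")]], numeric(1)))
  }
  # exact-membership atoms by Moebius inversion over supersets
  fractions <- vapply(subsets, function(m) {
    ss <- subsets[vapply(subsets, function(s) all(m %in% s), logical(1))]
    sum(vapply(ss, function(s) (-1)^(length(s) - length(m)) * imeas(s),
               numeric(1)))
  }, numeric(1))
  names(fractions) <- names(U)
  total <- U[[length(U)]]
  structure(list(fractions = fractions, residual = 1 - total,
                 total = total, adjusted = adjusted, subsets = U),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition (%s R^2):\n",
              if (x$adjusted) "adjusted" else "raw"))
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-12s %7.4f\n", nm, x$fractions[nm]))
  }
  cat(sprintf("  %-12s %7.4f\n", "residual", x$residual))
  invisible(x)
}

#' Distance-decay relationship
#'
#' OLS of community distance on geographic distance over the unordered
#' site pairs, with a Mantel-style permutation p-value: rows and columns
#' of the geographic matrix are permuted jointly and the one-sided
#' (positive-slope) add-one p-value is reported.
#'
#' @param d_comm,d_geo symmetric, conformable distance matrices.
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return list of class `distance_decay`: `slope`, `intercept`, `r2`,
#'   `p`, `n_pairs`.
#' @export
distance_decay <- function(d_comm, d_geo, n_perm = 999, seed = NULL) {
  d_comm <- as.matrix(d_comm)
  d_geo <- as.matrix(d_geo)
  if (!all(dim(d_comm) == dim(d_geo))) {
    stop_bb("distance matrices are not conformable", class = "shape_error")
  }
  ut <- upper.tri(d_comm)
  x <- d_geo[ut]
  y <- d_comm[ut]
  if (sd(x) == 0) {
    stop_bb("geographic distances are constant",
            class = "degenerate_regression")
  }
  slope_of <- function(xv) cov(xv, y) / var(xv)
  b <- slope_of(x)
  a <- mean(y) - b * mean(x)
  r2 <- cor(x, y)^2
  n <- nrow(d_geo)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      slope_of(d_geo[p, p][ut]) >= b
    }, logical(1)))
  })
  structure(list(slope = b, intercept = a, r2 = r2,
                 p = (1 + count) / (n_perm + 1), n_pairs = length(y)),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("Distance decay: slope %.4g, R^2 = %.3f, P = %.4g (%d pairs)\n",
              x$slope, x$r2, x$p, x$n_pairs))
  invisible(x)
}

#' Linear-vs-quadratic test for an alpha-diversity hump
#'
#' Fits degree-1 and degree-2 OLS polynomials of alpha diversity on the
#' browning value and compares them by `AIC = n log(SSE/n) + 2k`. When the
#' quadratic wins with a negative curvature and an interior vertex, the
#' peak position `-b/(2a)` is reported. This is the package's documented
#' parametric stand-in for spline smoothing of the hump.
#'
#' @param alpha per-site alpha-diversity values.
#' @param gradient per-site browning values (>= 6 sites, non-constant).
#' @return list of class `hump_test`: `aic_linear`, `aic_quadratic`,
#'   `winner` (`"linear"`/`"quadratic"`), `peak` (`NA` unless concave with
#'   an interior vertex), and the quadratic coefficients.
#' @export
alpha_hump_test <- function(alpha, gradient) {
  n <- length(alpha)
  if (n < 6) stop_bb("need >= 6 sites", class = "invalid_input")
  if (sd(gradient) == 0) {
    stop_bb("gradient is constant", class = "degenerate_regression")
  }
  aic_of <- function(fit, k) n * log(sum(fit$residuals^2) / n) + 2 * k
  f1 <- lm(alpha ~ gradient)
  f2 <- lm(alpha ~ gradient + I(gradient^2))
  aic1 <- aic_of(f1, 2)
  aic2 <- aic_of(f2, 3)
  co <- stats::coef(f2)
  a <- co[[3]]
  b <- co[[2]]
  peak <- NA_real_
  if (aic2 < aic1 && a < 0) {
    vertex <- -b / (2 * a)
    if (vertex > min(gradient) && vertex < max(gradient)) peak <- vertex
  }
  structure(list(aic_linear = aic1, aic_quadratic = aic2,
                 winner = if (aic2 < aic1) "quadratic" else "linear",
                 peak = peak, coefficients = co),
            class = "hump_test")
}

#' @export
print.hump_test <- function(x, ...) {
  cat(sprintf("Alpha-diversity hump test: %s wins (AIC %.2f vs %.2f)",
              x$winner, x$aic_linear, x$aic_quadratic))
  if (!is.na(x$peak)) cat(sprintf("; peak at g = %.3g", x$peak))
  cat("\n")
  invisible(x)
}
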