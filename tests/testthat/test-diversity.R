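test_that("Hellinger transform puts rows on the unit sphere", {
  expect_equal(unname(hellinger_transform(rbind(c(1, 1, 2)))[1, ]),
               c(0.5, 0.5, 0.70711), tolerance = 1e-5)
  expect_equal(unname(hellinger_transform(rbind(c(5, 0)))[1, ]), c(1, 0))
  expect_error(hellinger_transform(rbind(ok = c(1, 1), bad = c(0, 0))),
               class = "zero_row")

  m <- random_counts(10, 30, seed = 2)
  h <- hellinger_transform(m)
  expect_equal(unname(rowSums(h^2)), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(h), unname(as.matrix(vegan::decostand(m, "hellinger"))),
               ignore_attr = TRUE)
})

test_that("Bray-Curtis matches the closed form and its identities", {
  d <- bray_curtis(rbind(c(1, 0), c(0, 1)))
  expect_equal(d[1, 2], 1)
  expect_equal(bray_curtis(rbind(c(2, 2), c(1, 3)))[1, 2], 0.25)
  m <- random_counts(8, 25, seed = 3)
  d <- bray_curtis(m)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:3) expect_equal(d[i, i + 1], bc_pair(m[i, ], m[i + 1, ]))
  # appending all-zero taxa columns changes nothing
  expect_equal(bray_curtis(cbind(m, z1 = 0, z2 = 0)), d)
  # Bray-Curtis on Hellinger rows still bounded
  dh <- bray_curtis(hellinger_transform(m))
  expect_true(all(dh >= 0 & dh <= 1))
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))),
               class = "undefined_distance")
})

test_that("alpha diversity indices match their definitions", {
  a <- alpha_diversity(rbind(c(1, 1, 1, 1)),
                       c("richness", "shannon", "simpson", "inv_simpson"))
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$inv_simpson, 4)
  expect_equal(a$simpson, 0.75)
  expect_equal(a$richness, 4)

  b <- alpha_diversity(rbind(c(7, 0, 0)),
                       c("richness", "shannon", "simpson"))
  expect_equal(b$shannon, 0)
  expect_equal(b$simpson, 0)
  expect_equal(b$richness, 1)

  # configurable Shannon base
  a2 <- alpha_diversity(rbind(c(1, 1, 1, 1)), "shannon", shannon_base = 2)
  expect_equal(a2$shannon, 2)

  # Shannon maximal at uniform composition for fixed richness;
  # inverse Simpson bounded by richness
  m <- random_counts(12, 20, seed = 5)
  al <- alpha_diversity(m, c("richness", "shannon", "inv_simpson"))
  expect_true(all(al$shannon <= log(al$richness) + 1e-12))
  expect_true(all(al$inv_simpson <= al$richness + 1e-12))
  expect_error(alpha_diversity(rbind(c(0, 0))), class = "zero_row")
})

test_that("Fisher's alpha solves its defining equation", {
  row <- c(rep(1, 5), rep(2, 5), rep(10, 10))  # S = 20, N = 115
  a <- fisher_alpha(row)
  expect_equal(a * log1p(sum(row) / a), 20, tolerance = 1e-8)
  # dense grid-scan oracle for S = 20, N = 100
  grid <- seq(0.1, 200, by = 1e-3)
  oracle <- grid[which.min(abs(grid * log1p(100 / grid) - 20))]
  row2 <- c(rep(1, 19), 81)
  expect_equal(fisher_alpha(row2), oracle, tolerance = 1e-3)
  expect_equal(unname(vegan::fisher.alpha(matrix(row2, 1))),
               fisher_alpha(row2), tolerance = 1e-4)
  expect_error(fisher_alpha(c(1, 1, 1)), class = "no_solution")  # S = N
  expect_error(fisher_alpha(c(5)), class = "no_solution")
})

test_that("ACE follows the Chao-Lee formula with explicit components", {
  r <- ace_richness(c(1, 1, 2, 3, 12))
  # independent evaluation: S_abund 1, S_rare 4, F1 2, N_rare 7,
  # C = 5/7, gamma2 = (4/(5/7)) * 8/42 - 1 = 1/15
  expect_equal(r$C_ace, 5 / 7)
  expect_equal(r$gamma2, 1 / 15, tolerance = 1e-12)
  expect_equal(r$ace, 1 + 4 / (5 / 7) + (2 / (5 / 7)) * (1 / 15),
               tolerance = 1e-12)
  expect_equal(r$ace, 6.7866667, tolerance = 1e-6)

  expect_equal(ace_richness(c(20, 30, 40))$ace, 3)  # no rare taxa
  expect_error(ace_richness(c(1, 1, 1)), class = "estimator_undefined")

  # vegan cross-check on a random row
  row <- withr::with_seed(7, rpois(60, 4) + 1L)
  expect_equal(ace_richness(row)$ace,
               unname(vegan::estimateR(row)["S.ACE"]), tolerance = 1e-6)
})

test_that("expected rarefaction matches combinatorics and Monte Carlo", {
  row <- c(10, 5, 2, 8)
  expect_equal(rarefy_expected(row, sum(row)), 4)
  expect_equal(rarefy_expected(c(4, 1), 2), 1.4, tolerance = 1e-12)
  expect_error(rarefy_expected(row, 26), class = "invalid_depth")

  # nondecreasing in depth; E[S_1] = 1
  vals <- vapply(1:25, function(n) rarefy_expected(row, n), numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) >= -1e-12))

  # Monte-Carlo oracle: (50, 30, 20), n = 25, 10000 subsamples
  row2 <- c(50, 30, 20)
  pool <- rep(1:3, row2)
  sims <- withr::with_seed(11, vapply(1:10000, function(i) {
    length(unique(sample(pool, 25)))
  }, numeric(1)))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(rarefy_expected(row2, 25) - mean(sims)), 3 * se)
})

test_that("rarefaction subsampling keeps the hypergeometric margins", {
  m <- tiny_counts()
  sub <- rarefy_subsample(m, seed = 1)       # default: min row sum rule
  expect_equal(unname(rowSums(sub)), rep(min(rowSums(m)), 3))
  expect_true(all(sub <= m))
  expect_identical(rarefy_subsample(m, 8, seed = 2),
                   rarefy_subsample(m, 8, seed = 2))
  full <- rarefy_subsample(m[1, , drop = FALSE], sum(m[1, ]), seed = 1)
  expect_identical(unname(full[1, ]), unname(m[1, ]))
  expect_error(rarefy_subsample(m, 100), class = "invalid_depth")

  # cell means over 5000 replicates vs hypergeometric expectation (4 SE)
  row <- matrix(c(30L, 20L), 1, dimnames = list("s", c("x", "y")))
  draws <- vapply(1:5000, function(i) rarefy_subsample(row, 10)[1, 1],
                  numeric(1))
  mu <- 10 * 30 / 50
  v <- 10 * (30 / 50) * (20 / 50) * (50 - 10) / (50 - 1)
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / 5000))
})

test_that("exact species accumulation equals the permutation mean", {
  # a taxon present at every site contributes exactly 1 for all m
  m <- cbind(everywhere = rep(5L, 6), random_counts(6, 10, lambda = 1,
                                                    seed = 13))
  curve <- species_accum_exact(m)
  expect_equal(curve$m, 1:6)
  expect_true(all(diff(curve$richness) >= -1e-12))
  expect_equal(curve$richness[6], sum(colSums(m > 0) > 0))
  expect_equal(curve$richness[1], mean(rowSums(m > 0)))

  # permutation oracle: 2000 random site orderings
  sims <- withr::with_seed(17, vapply(1:2000, function(i) {
    ord <- sample(nrow(m))
    vapply(1:6, function(k) sum(colSums(m[ord[1:k], , drop = FALSE]) > 0),
           numeric(1))
  }, numeric(6)))
  for (k in 1:6) {
    se <- sd(sims[k, ]) / sqrt(ncol(sims))
    expect_lt(abs(curve$richness[k] - mean(sims[k, ])), max(3 * se, 1e-9))
  }
})

test_that("CDOM PCA index matches an eigendecomposition and conventions", {
  g <- c(0.5, 2, 5, 8, 11, 12)
  sp <- make_spectra(g, noise_sd = 0)
  # rank-1 data: PC1 carries all variance when unscaled
  p0 <- cdom_pca_index(sp, scale = FALSE)
  expect_equal(p0$variance_fraction[1], 1, tolerance = 1e-9)

  spn <- make_spectra(g, S_decay = 0.005, noise_sd = 0.01, seed = 3)
  p <- cdom_pca_index(spn, scale = TRUE)
  expect_true(all(abs(colMeans(p$scores)) < 1e-9))
  expect_gte(cor(p$scores[, 1], rowMeans(spn)), 0)
  # eigen oracle on the scaled covariance
  ev <- eigen(cov(scale(spn)), symmetric = TRUE)
  expect_equal(p$variance_fraction,
               (ev$values / sum(ev$values))[seq_along(p$variance_fraction)],
               tolerance = 1e-9)
  expect_equal(abs(cor(p$scores[, 1], scale(spn) %*% ev$vectors[, 1])[1]), 1,
               tolerance = 1e-9)

  # duplicating every row leaves the variance fractions unchanged
  pdup <- cdom_pca_index(rbind(spn, spn), scale = TRUE)
  expect_equal(pdup$variance_fraction, p$variance_fraction, tolerance = 1e-9)

  expect_error(cdom_pca_index(cbind(sp, const = 1), scale = TRUE),
               class = "degenerate_column")
  expect_error(cdom_pca_index(sp[1, , drop = FALSE]),
               class = "invalid_spectra")
})
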