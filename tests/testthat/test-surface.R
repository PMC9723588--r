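test_that("pair dataset construction enumerates site pairs correctly", {
  g <- c(1, 2, 4, 7)
  d <- bray_curtis(tiny_counts()[c(1, 2, 3, 1), ] + 1L)
  p <- build_pair_dataset(g, d)
  expect_equal(nrow(p), 12)                      # 4 * 3 ordered pairs
  p1 <- build_pair_dataset(g, d, symmetric = FALSE)
  expect_equal(nrow(p1), 6)                      # C(4, 2)
  expect_true(all(p$site1 != p$site2))
  key <- paste(pmin(p$site1, p$site2), pmax(p$site1, p$site2))
  mirrored <- tapply(p$d, key, function(v) diff(range(v)))
  expect_true(all(mirrored == 0))
  expect_error(build_pair_dataset(g[1:3], d), class = "shape_error")
})

test_that("train/test split is exhaustive, seeded and leak-free", {
  sc <- linear_pair_scenario(n_sites = 16, seed = 2)
  pairs <- build_pair_dataset(sc$g, sc$d)       # 240 rows, 120 unordered
  f <- split_train_test(pairs, 0.8, seed = 1)
  expect_equal(nrow(f$train) + nrow(f$test), nrow(pairs))
  expect_equal(nrow(f$train), 2 * round(0.8 * 120))
  f2 <- split_train_test(pairs, 0.8, seed = 1)
  expect_identical(f$train$d, f2$train$d)
  # mirrored pairs stay in the same fold
  key <- function(df) paste(pmin(df$site1, df$site2),
                            pmax(df$site1, df$site2))
  expect_length(intersect(key(f$train), key(f$test)), 0)
  expect_error(split_train_test(pairs[1:3, ]), class = "split_error")
})

test_that("gradient boosting honours its contracts", {
  sc <- linear_pair_scenario(n_sites = 20, seed = 3)
  pairs <- build_pair_dataset(sc$g, sc$d)

  m0 <- fit_gradient_boost(pairs, rounds = 0)
  expect_equal(unique(predict(m0, pairs)), mean(pairs$d))

  # piecewise-constant noiseless target with 4 blocks: exact fit reachable
  g <- rep(c(1, 2, 5, 6), each = 5) + rep(seq(0, 0.4, 0.1), 4)
  dblock <- outer(g, g, function(u, v) {
    0.2 + 0.3 * (u > 3) + 0.25 * (v > 3)
  })
  diag(dblock) <- 0
  dblock <- (dblock + t(dblock)) / 2
  pb <- build_pair_dataset(g, dblock)
  mb <- fit_gradient_boost(pb, rounds = 20, depth = 2, learning_rate = 1,
                           lambda = 0)
  expect_lt(mb$train_mse[20], 1e-10)

  # training MSE non-increasing per round
  m <- fit_gradient_boost(pairs, rounds = 60)
  expect_true(all(diff(m$train_mse) <= 1e-12))

  expect_error(fit_gradient_boost(pairs, learning_rate = 0),
               class = "invalid_hyperparameter")
})

test_that("a single stump finds the exhaustive best SSE split", {
  withr::with_seed(5, {
    X <- cbind(g1 = runif(40), g2 = runif(40))
    y <- runif(40)
  })
  train <- data.frame(g1 = X[, 1], g2 = X[, 2], d = y)
  stump <- fit_gradient_boost(train, rounds = 1, depth = 1,
                              learning_rate = 1, lambda = 0)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (f in 1:2) {
    for (cut in sort(unique(X[, f]))[-1]) {
      left <- X[, f] < cut
      best <- min(best, sse(y[left]) + sse(y[!left]))
    }
  }
  expect_equal(sum((y - predict(stump, train))^2), best, tolerance = 1e-9)
})

test_that("random forests average their trees deterministically", {
  sc <- linear_pair_scenario(n_sites = 15, seed = 7)
  pairs <- build_pair_dataset(sc$g, sc$d)
  const <- pairs
  const$d <- 0.42
  mc <- fit_random_forest(const, n_trees = 5, seed = 1)
  expect_equal(unique(predict(mc, const)), 0.42)

  m <- fit_random_forest(pairs, n_trees = 7, seed = 2)
  q <- withr::with_seed(3, data.frame(g1 = runif(50, 0, 12),
                                      g2 = runif(50, 0, 12)))
  pm <- predict(m, q)
  per_tree <- sapply(m$trees, function(tr) {
    betabrowning:::.predict_tree_cpp(tr, cbind(q$g1, q$g2))
  })
  expect_equal(pm, rowMeans(per_tree), tolerance = 1e-12)

  expect_identical(predict(fit_random_forest(pairs, n_trees = 7, seed = 2), q),
                   pm)
  # one unbootstrapped tree with all features is a plain regression tree
  t1 <- fit_random_forest(pairs, n_trees = 1, bootstrap = FALSE, seed = 9)
  t2 <- fit_random_forest(pairs, n_trees = 1, bootstrap = FALSE, seed = 10)
  expect_equal(predict(t1, q), predict(t2, q))
})

test_that("the FFNN honours Xavier initialisation and learns", {
  sc <- linear_pair_scenario(n_sites = 15, seed = 11)
  pairs <- build_pair_dataset(sc$g, sc$d)
  m <- fit_ffnn(pairs, layer_sizes = c(8), epochs = 200,
                learning_rate = 0.01, seed = 1)
  for (layer in m$initial_layers) {
    expect_true(all(abs(layer$W) <= layer$bound + 1e-12))
    expect_true(all(layer$b == 0))
  }
  expect_lt(m$loss[length(m$loss)], m$loss[1])

  # zero hidden layers: gradient descent approaches the OLS optimum
  mlin <- fit_ffnn(pairs, layer_sizes = integer(0), epochs = 400,
                   learning_rate = 0.02, seed = 2)
  A <- cbind(1, scale(cbind(pairs$g1, pairs$g2)))
  ols_mse <- mean(lm.fit(A, pairs$d)$residuals^2)
  expect_lt(mlin$loss[length(mlin$loss)], ols_mse * 1.05)
  expect_error(fit_ffnn(pairs, epochs = 0), class = "invalid_hyperparameter")
})

test_that("polynomial OLS-by-SVD matches the normal equations", {
  sc <- linear_pair_scenario(n_sites = 15, noise_sd = 0, seed = 13)
  pairs <- build_pair_dataset(sc$g, sc$d)
  m0 <- fit_polynomial(pairs, 0)
  expect_equal(unique(round(predict(m0, pairs), 12)),
               round(mean(pairs$d), 12))
  m1 <- fit_polynomial(pairs, 1)
  expect_lt(max(abs(residuals(m1))), 1e-9)     # exactly linear target

  sc2 <- linear_pair_scenario(n_sites = 20, noise_sd = 0.05, seed = 14)
  p2 <- build_pair_dataset(sc2$g, sc2$d)
  m2 <- fit_polynomial(p2, 2)
  A <- betabrowning:::poly_design(p2$g1, p2$g2, 2)
  beta <- solve(crossprod(A), crossprod(A, p2$d))
  expect_equal(unname(coef(m2)), as.numeric(beta), tolerance = 1e-8)
})

test_that("degree selection follows the bias-variance decomposition", {
  sc <- linear_pair_scenario(n_sites = 20, noise_sd = 0, seed = 15)
  pairs <- build_pair_dataset(sc$g, sc$d)
  sel <- select_degree(pairs, degrees = 1:4, n_resamples = 30, seed = 1)
  expect_equal(sel$chosen, 1)   # noiseless linear: ties go to the lowest
  # exact decomposition: error = bias^2 + variance (population variance)
  expect_equal(sel$curves$error,
               sel$curves$bias2 + sel$curves$variance, tolerance = 1e-12)

  # cubic surface + noise: chosen degree lands in [2, 5] almost always
  hits <- 0
  for (s in 1:20) {
    g <- withr::with_seed(300 + s, runif(18, 0, 2))
    d3 <- outer(g, g, function(u, v) 0.1 * (u - 1)^3 + 0.1 * (v - 1)^3 + 0.4)
    d3 <- (d3 + t(d3)) / 2 +
      withr::with_seed(400 + s, matrix(rnorm(18^2, 0, 0.01), 18))
    d3 <- (d3 + t(d3)) / 2
    diag(d3) <- 0
    ps <- build_pair_dataset(g, pmin(pmax(d3, 0), 1))
    ch <- select_degree(ps, degrees = 1:6, n_resamples = 25,
                        seed = 500 + s)$chosen
    hits <- hits + (ch >= 2 && ch <= 5)
  }
  expect_gte(hits, 18)
})

test_that("meshgrid prediction implements the step rule with a cap", {
  sc <- linear_pair_scenario(n_sites = 10, seed = 17)
  pairs <- build_pair_dataset(sc$g, sc$d)
  m0 <- fit_gradient_boost(pairs, rounds = 0)

  surf <- predict_meshgrid(m0, c(1, 2, 4))
  expect_equal(surf$axis, c(1, 2, 3, 4))
  expect_equal(surf$step, 1)
  expect_equal(unique(as.numeric(surf$values)), mean(pairs$d))
  expect_equal(surf$baseline, mean(pairs$d))

  expect_warning(big <- predict_meshgrid(m0, c(0, 1e-5, 1), max_grid = 100),
                 "capped")
  expect_length(big$axis, 100)
  expect_error(predict_meshgrid(m0, c(2, 2, 2)),
               class = "degenerate_gradient")
})

test_that("model evaluation computes fold-local MSE and R squared", {
  toy <- data.frame(g1 = c(1, 2, 3, 4, 5), g2 = c(5, 4, 3, 2, 1),
                    d = c(0.2, 0.4, 0.3, 0.8, 0.6))
  m <- fit_polynomial(toy, 1)
  te <- data.frame(g1 = c(1.5, 3.5), g2 = c(4, 2), d = c(0.35, 0.55))
  met <- evaluate_model(m, te)
  pred <- predict(m, te)
  expect_equal(met$test_mse, mean((te$d - pred)^2), tolerance = 1e-12)
  expect_equal(met$test_r2,
               1 - sum((te$d - pred)^2) / sum((te$d - mean(te$d))^2),
               tolerance = 1e-12)

  # perfect prediction and the mean-only predictor
  sc <- linear_pair_scenario(n_sites = 12, noise_sd = 0, seed = 19)
  pairs <- build_pair_dataset(sc$g, sc$d)
  perfect <- evaluate_model(fit_polynomial(pairs, 1), pairs)
  expect_equal(perfect$test_r2, 1, tolerance = 1e-9)
  expect_lt(perfect$test_mse, 1e-18)
  mean_only <- evaluate_model(fit_gradient_boost(pairs, rounds = 0), pairs)
  expect_equal(mean_only$train_r2, 0, tolerance = 1e-12)

  const <- pairs[1:6, ]
  const$d <- 0.5
  expect_warning(res <- evaluate_model(fit_polynomial(pairs, 1), const),
                 "undefined")
  expect_true(is.na(res$test_r2))
  expect_false(is.na(res$test_mse))
})
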