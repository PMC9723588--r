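test_that("RDA R-squared matches its linear-algebra definition", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
    B <- matrix(rnorm(3 * 6), 3)
    Y <- scale(X, scale = FALSE) %*% B          # exact linear map
  })
  fit <- rda_r2(Y, X)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # response orthogonal to the predictors
  withr::with_seed(2, {
    x <- rnorm(30)
    y <- stats::residuals(lm(rnorm(30) ~ x))
  })
  expect_lt(rda_r2(matrix(y), matrix(x, dimnames = list(NULL, "x")))$r2,
            1e-12)

  # Ezekiel adjustment against an independent recomputation
  withr::with_seed(3, {
    for (i in 1:50) {
      n <- sample(15:40, 1)
      p <- sample(1:4, 1)
      X <- matrix(rnorm(n * p), n)
      Y <- matrix(rnorm(n * 5), n)
      f <- rda_r2(Y, X)
      expect_equal(f$adj_r2, 1 - (1 - f$r2) * (n - 1) / (n - p - 1),
                   tolerance = 1e-12)
      # and r2 against a direct lm fit
      r2_lm <- sum(qr.fitted(qr(scale(X)), scale(Y, scale = FALSE))^2) /
        sum(scale(Y, scale = FALSE)^2)
      expect_equal(f$r2, r2_lm, tolerance = 1e-12)
    }
  })

  X <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("u", "dup")))
  X[, 2] <- 2 * X[, 1]
  expect_error(rda_r2(matrix(rnorm(20)), X), regexp = "dup",
               class = "collinearity_error")
})

test_that("variance partitioning obeys inclusion-exclusion", {
  withr::with_seed(5, {
    X1 <- matrix(rnorm(50 * 2), 50, dimnames = list(NULL, c("a1", "a2")))
    X2 <- matrix(rnorm(50 * 2), 50, dimnames = list(NULL, c("b1", "b2")))
    X3 <- matrix(rnorm(50), 50, dimnames = list(NULL, "c1"))
    Y <- X1 %*% matrix(rnorm(2 * 8), 2) + matrix(rnorm(50 * 8, 0, 0.5), 50)
  })
  # raw-R2 fractions: identity to machine precision, 2 and 3 sets
  for (sets in list(list(A = X1, B = X2), list(A = X1, B = X2, C = X3))) {
    vp <- variance_partition(Y, sets, adjusted = FALSE)
    expect_equal(sum(vp$fractions) + vp$residual, 1, tolerance = 1e-9)
    expect_equal(sum(vp$fractions), vp$total, tolerance = 1e-9)
  }
  vpa <- variance_partition(Y, list(A = X1, B = X2), adjusted = TRUE)
  expect_equal(sum(vpa$fractions) + vpa$residual, 1, tolerance = 1e-9)

  # duplicated predictor set: unique fractions vanish, everything is shared
  dup <- variance_partition(Y, list(A = X1, B = X1 * 2), adjusted = FALSE)
  expect_lt(abs(dup$fractions[["A"]]), 1e-9)
  expect_lt(abs(dup$fractions[["B"]]), 1e-9)
  expect_equal(dup$fractions[["A&B"]], dup$total, tolerance = 1e-9)
  dupa <- variance_partition(Y, list(A = X1, B = X1 * 2), adjusted = TRUE)
  expect_lt(abs(dupa$fractions[["A"]]), 0.02)

  # nested models: unadjusted R2 nondecreasing with added predictors
  expect_gte(vp$subsets[["A&B"]], vp$subsets[["A"]] - 1e-12)
  expect_gte(vp$subsets[["A&B"]], vp$subsets[["B"]] - 1e-12)

  expect_error(variance_partition(Y, list(X1)), class = "invalid_input")
})

test_that("variance partitioning agrees with vegan::varpart", {
  withr::with_seed(6, {
    X1 <- matrix(rnorm(40 * 2), 40, dimnames = list(NULL, c("a1", "a2")))
    X2 <- matrix(rnorm(40 * 2), 40, dimnames = list(NULL, c("b1", "b2")))
    Y <- X1 %*% matrix(rnorm(2 * 6), 2) + 0.5 * X2 %*% matrix(rnorm(2 * 6), 2) +
      matrix(rnorm(40 * 6), 40)
  })
  vp <- variance_partition(Y, list(A = X1, B = X2), adjusted = TRUE)
  vref <- vegan::varpart(Y, X1, X2)$part$indfract$Adj.R.square
  expect_equal(unname(vp$fractions[c("A", "B", "A&B")]), vref[1:3],
               tolerance = 1e-6)
  expect_equal(vp$residual, vref[4], tolerance = 1e-6)
})

test_that("an independent noise predictor set explains nothing unique", {
  devs <- vapply(1:20, function(s) {
    withr::with_seed(700 + s, {
      X1 <- matrix(rnorm(60), 60, dimnames = list(NULL, "g"))
      X2 <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("n1", "n2")))
      Y <- X1 %*% matrix(rnorm(10), 1) + matrix(rnorm(60 * 10, 0, 0.8), 60)
    })
    variance_partition(Y, list(signal = X1, noise = X2),
                       adjusted = TRUE)$fractions[["noise"]]
  }, numeric(1))
  expect_true(all(abs(devs) <= 0.03))
})

test_that("distance decay recovers exact relationships and calibrated nulls", {
  withr::with_seed(9, {
    n <- 18
    xy <- matrix(runif(2 * n, 0, 100), n)
  })
  dg <- as.matrix(dist(xy))
  dc <- 0.1 + 0.02 * dg
  diag(dc) <- 0
  dd <- distance_decay(dc, dg, n_perm = 199, seed = 1)
  expect_equal(dd$slope, 0.02, tolerance = 1e-10)
  expect_equal(dd$r2, 1, tolerance = 1e-10)
  expect_lte(dd$p, 0.01)

  expect_error(distance_decay(dc, matrix(1, n, n) - diag(n)),
               class = "degenerate_regression")

  # null calibration: independent matrices give approximately uniform p
  ps <- vapply(1:300, function(i) {
    withr::with_seed(2000 + i, {
      a <- as.matrix(dist(rnorm(12)))
      b <- as.matrix(dist(rnorm(12)))
    })
    distance_decay(a, b, n_perm = 199, seed = 3000 + i)$p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.1)
})

test_that("the hump test separates linear and concave responses", {
  g <- seq(0, 10, length.out = 25)
  ht <- alpha_hump_test(-(g - 5)^2 + 40, g)
  expect_equal(ht$winner, "quadratic")
  expect_equal(ht$peak, 5, tolerance = 1e-9)

  withr::with_seed(12, {
    lin <- alpha_hump_test(2 * g + rnorm(25, 0, 0.1), g)
  })
  expect_equal(lin$winner, "linear")
  expect_true(is.na(lin$peak))

  # AIC formula check: n log(SSE/n) + 2k
  y <- -(g - 4)^2 + g + 30
  ht2 <- alpha_hump_test(y, g)
  f1 <- lm(y ~ g)
  expect_equal(ht2$aic_linear,
               25 * log(sum(stats::residuals(f1)^2) / 25) + 4,
               tolerance = 1e-12)

  expect_error(alpha_hump_test(1:5, 1:5), class = "invalid_input")
  expect_error(alpha_hump_test(rnorm(10), rep(1, 10)),
               class = "degenerate_regression")

  # standard synthetic scenario: richness humps at intermediate browning
  wins <- 0
  for (s in 1:20) {
    ds <- simulate_browning_dataset(seed = 500 + s)
    rich <- rowSums(ds$counts > 0)
    ht <- alpha_hump_test(rich, ds$site_table$gradient_value)
    wins <- wins + (ht$winner == "quadratic" && !is.na(ht$peak))
  }
  expect_gte(wins, 16)   # >= 80% of 20 seeds
})
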