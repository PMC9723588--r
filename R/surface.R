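#' Build the pairwise regression dataset
#'
#' Turns a site-by-site distance matrix and the per-site browning values
#' into regression rows `(g_site1, g_site2) -> distance`. Self-pairs are
#' excluded; in symmetric mode both orderings of every pair are included
#' (with equal distance), which encourages fitted surfaces to be symmetric
#' about the diagonal.
#'
#' @param gradient per-site browning values.
#' @param distances symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param symmetric include both orderings of each pair (default `TRUE`).
#' @return data.frame of class `pair_dataset` with columns `site1`,
#'   `site2`, `g1`, `g2`, `d`.
#' @export
build_pair_dataset <- function(gradient, distances, symmetric = TRUE) {
  distances <- as.matrix(distances)
  n <- length(gradient)
  if (nrow(distances) != n || ncol(distances) != n) {
    stop_bb("gradient length (%d) must match distance matrix dimension (%d)",
            n, nrow(distances), class = "shape_error")
  }
  ij <- which(upper.tri(distances), arr.ind = TRUE)
  out <- data.frame(site1 = ij[, 1], site2 = ij[, 2],
                    g1 = gradient[ij[, 1]], g2 = gradient[ij[, 2]],
                    d = distances[ij])
  if (symmetric) {
    mirror <- data.frame(site1 = out$site2, site2 = out$site1,
                         g1 = out$g2, g2 = out$g1, d = out$d)
    out <- rbind(out, mirror)
  }
  structure(out, class = c("pair_dataset", "data.frame"),
            symmetric = symmetric)
}

#' Split pairs into training and test folds
#'
#' Samples unordered site pairs, so that in symmetric mode the two mirrored
#' rows of a pair always land in the same fold (otherwise the identical
#' target would leak across folds).
#'
#' @param pairs a [build_pair_dataset()] result.
#' @param train_frac training fraction (default 0.8).
#' @param seed optional integer seed.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(pairs, train_frac = 0.8, seed = NULL) {
  if (nrow(pairs) < 5) stop_bb("too few rows to split", class = "split_error")
  key <- paste(pmin(pairs$site1, pairs$site2),
               pmax(pairs$site1, pairs$site2))
  uk <- unique(key)
  n_train <- round(train_frac * length(uk))
  tr_keys <- with_seed(seed, sample(uk, n_train))
  tr <- key %in% tr_keys
  list(train = pairs[tr, , drop = FALSE],
       test = pairs[!tr, , drop = FALSE])
}

pair_xy <- function(pairs) {
  X <- cbind(g1 = pairs$g1, g2 = pairs$g2)
  list(X = X, y = pairs$d)
}

new_beta_surface <- function(method, pairs, fitted, extra) {
  structure(c(list(method = method,
                   train = pairs[, c("g1", "g2", "d")],
                   fitted_values = fitted),
              extra),
            class = c(paste0(method, "_surface"), "beta_surface"))
}

#' Gradient-boosted regression-tree surface
#'
#' Additive ensemble of depth-limited regression trees fitted to squared
#' loss. Each round fits a tree to the current residuals; because squared
#' loss has unit Hessian, the Newton leaf weight is
#' `sum(residuals) / (count + lambda)` and the update is shrunk by the
#' learning rate. The base score is the training mean, so zero rounds
#' predict the mean everywhere, and training MSE is non-increasing over
#' rounds for `lambda >= 0` and learning rate in (0, 1].
#'
#' @param train a `pair_dataset` (or data.frame with `g1`, `g2`, `d`).
#' @param rounds boosting rounds (>= 0; default 300).
#' @param depth maximum tree depth (default 3).
#' @param learning_rate shrinkage nu in (0, 1] (default 0.1).
#' @param lambda L2 penalty on leaf weights (default 1).
#' @param seed unused by the deterministic fit; accepted for interface
#'   uniformity.
#' @return object of class `c("gbt_surface", "beta_surface")`; the
#'   element `train_mse` holds the per-round training MSE path.
#' @export
fit_gradient_boost <- function(train, rounds = 300, depth = 3,
                               learning_rate = 0.1, lambda = 1,
                               seed = NULL) {
  if (learning_rate <= 0) {
    stop_bb("learning_rate must be > 0", class = "invalid_hyperparameter")
  }
  if (rounds < 0) stop_bb("rounds must be >= 0",
                          class = "invalid_hyperparameter")
  xy <- pair_xy(train)
  base <- mean(xy$y)
  pred <- rep(base, length(xy$y))
  trees <- vector("list", rounds)
  mse <- numeric(rounds)
  for (r in seq_len(rounds)) {
    resid <- xy$y - pred
    tree <- .fit_tree_cpp(xy$X, resid, seq_along(xy$y), depth, 2L,
                          lambda, ncol(xy$X))
    pred <- pred + learning_rate * .predict_tree_cpp(tree, xy$X)
    trees[[r]] <- tree
    mse[r] <- mean((xy$y - pred)^2)
  }
  new_beta_surface("gbt", train, pred,
                   list(trees = trees, base_score = base,
                        rounds = rounds, depth = depth,
                        learning_rate = learning_rate, lambda = lambda,
                        train_mse = mse))
}

#' Random-forest surface
#'
#' Mean of fully grown (down to `min_node`) regression trees, each fitted
#' on a bootstrap resample with an optional random feature subset per node.
#' With `bootstrap = FALSE`, all features, and one tree, the forest is a
#' single regression tree on the training data.
#'
#' @inheritParams fit_gradient_boost
#' @param n_trees number of trees (default 100).
#' @param bootstrap resample rows with replacement per tree.
#' @param feature_subset features tried per split (default: all).
#' @param min_node smallest node that may still be split (default 5).
#' @param seed integer seed; same seed gives an identical forest.
#' @return object of class `c("random_forest_surface", "beta_surface")`.
#' @export
fit_random_forest <- function(train, n_trees = 100, bootstrap = TRUE,
                              feature_subset = NULL, min_node = 5,
                              seed = NULL) {
  if (n_trees < 1) stop_bb("n_trees must be >= 1",
                           class = "invalid_hyperparameter")
  xy <- pair_xy(train)
  n <- length(xy$y)
  mtry <- if (is.null(feature_subset)) ncol(xy$X) else as.integer(feature_subset)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      .fit_tree_cpp(xy$X, xy$y, rows, -1L, as.integer(min_node), 0, mtry)
    })
  })
  fitted <- .predict_ensemble_cpp(trees, xy$X,
                                  rep(1 / n_trees, n_trees), 0)
  new_beta_surface("random_forest", train, fitted,
                   list(trees = trees, n_trees = n_trees,
                        bootstrap = bootstrap, feature_subset = mtry,
                        min_node = min_node))
}

xavier_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    bound <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -bound, bound),
                    fan_in, fan_out),
         b = rep(0, fan_out), bound = bound)
  })
}

ffnn_forward <- function(layers, X) {
  acts <- list(X)
  a <- X
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- a %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(a))
    a <- if (l < L) pmax(z, 0) else z  # ReLU hidden, linear output
    acts[[l + 1]] <- a
  }
  acts
}

#' Feed-forward neural-network surface
#'
#' Fully connected network with ReLU hidden activations, a linear output,
#' Xavier-uniform initial weights (bounded by `sqrt(6 / (fan_in +
#' fan_out))`), mean-squared-error loss, and plain mini-batch gradient
#' descent by backpropagation. Inputs are z-scored internally. An empty
#' `layer_sizes` gives a linear model trained by gradient descent.
#'
#' @inheritParams fit_gradient_boost
#' @param layer_sizes hidden-layer widths (default `c(16, 16)`).
#' @param epochs training epochs (>= 1; default 500).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed for initialisation and batch shuffling.
#' @return object of class `c("ffnn_surface", "beta_surface")`; elements
#'   `initial_layers` and `loss` expose the Xavier draws and the per-epoch
#'   training MSE.
#' @export
fit_ffnn <- function(train, layer_sizes = c(16, 16), epochs = 500,
                     learning_rate = 0.01, batch_size = 32, seed = NULL) {
  if (epochs < 1) stop_bb("epochs must be >= 1",
                          class = "invalid_hyperparameter")
  xy <- pair_xy(train)
  center <- colMeans(xy$X)
  scl <- apply(xy$X, 2, sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(xy$X, 2, center), 2, scl, "/")
  y <- xy$y
  n <- nrow(X)
  sizes <- c(ncol(X), layer_sizes, 1)
  with_seed(seed, {
    layers <- xavier_init(sizes)
    initial <- layers
    L <- length(layers)
    loss <- numeric(epochs)
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, n)]
        acts <- ffnn_forward(layers, X[rows, , drop = FALSE])
        m <- length(rows)
        delta <- 2 * (acts[[L + 1]] - y[rows]) / m  # dMSE/dz_out
        for (l in L:1) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
          }
          layers[[l]]$W <- layers[[l]]$W - learning_rate * gW
          layers[[l]]$b <- layers[[l]]$b - learning_rate * gb
        }
      }
      out <- ffnn_forward(layers, X)[[L + 1]]
      loss[e] <- mean((out - y)^2)
      if (!is.finite(loss[e])) {
        stop_bb("FFNN training diverged at epoch %d (non-finite loss)", e,
                class = "divergence_error")
      }
    }
    fitted <- as.numeric(ffnn_forward(layers, X)[[L + 1]])
    new_beta_surface("ffnn", train, fitted,
                     list(layers = layers, initial_layers = initial,
                          layer_sizes = layer_sizes, epochs = epochs,
                          learning_rate = learning_rate,
                          batch_size = batch_size, center = center,
                          scale = scl, loss = loss))
  })
}

poly_design <- function(g1, g2, degree) {
  ab <- expand.grid(a = 0:degree, b = 0:degree)
  ab <- ab[ab$a + ab$b <= degree, , drop = FALSE]
  A <- mapply(function(a, b) g1^a * g2^b, ab$a, ab$b)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  colnames(A) <- paste0("g1^", ab$a, "*g2^", ab$b)
  A
}

#' Polynomial (OLS by SVD) baseline surface
#'
#' Ordinary least squares on all monomials `g1^a * g2^b` with
#' `a + b <= degree`, solved through the singular value decomposition;
#' singular values below `rcond` times the largest are dropped
#' (pseudoinverse), so near-collinear designs stay stable.
#'
#' @inheritParams fit_gradient_boost
#' @param degree polynomial degree (>= 0).
#' @param rcond relative singular-value cutoff (default 1e-10).
#' @return object of class `c("polynomial_surface", "beta_surface")`;
#'   `coef()` returns the monomial coefficients.
#' @export
fit_polynomial <- function(train, degree, rcond = 1e-10) {
  if (degree < 0) stop_bb("degree must be >= 0",
                          class = "invalid_hyperparameter")
  xy <- pair_xy(train)
  if (length(xy$y) < 1) stop_bb("no rows to fit", class = "fit_error")
  A <- poly_design(xy$X[, 1], xy$X[, 2], degree)
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coefs <- sv$v %*% (dinv * crossprod(sv$u, xy$y))
  coefs <- stats::setNames(as.numeric(coefs), colnames(A))
  fitted <- as.numeric(A %*% coefs)
  new_beta_surface("polynomial", train, fitted,
                   list(coefficients = coefs, degree = degree,
                        rcond = rcond))
}

#' Choose the polynomial degree by the bias-variance trade-off
#'
#' For every candidate degree, refits the polynomial on bootstrap
#' resamples of the training fold and evaluates on a held-out test fold.
#' The test error decomposes exactly (population variance over resamples)
#' into `error = bias2 + variance`, where the squared-bias term is taken
#' against the observed test targets and therefore absorbs the noise
#' floor. The chosen degree minimises mean test error; ties go to the
#' lowest degree.
#'
#' @param pairs a `pair_dataset`.
#' @param degrees candidate degrees (default 0:6).
#' @param n_resamples bootstrap resamples per degree (default 50).
#' @param train_frac training fraction for the internal split.
#' @param seed integer seed.
#' @return list with `chosen` and a data.frame `curves` (degree, error,
#'   bias2, variance).
#' @export
select_degree <- function(pairs, degrees = 0:6, n_resamples = 50,
                          train_frac = 0.8, seed = NULL) {
  if (length(degrees) < 2) stop_bb("need >= 2 candidate degrees",
                                   class = "invalid_hyperparameter")
  with_seed(seed, {
    folds <- split_train_test(pairs, train_frac)
    tr <- folds$train
    te <- folds$test
    n_tr <- nrow(tr)
    curves <- lapply(degrees, function(dg) {
      preds <- vapply(seq_len(n_resamples), function(b) {
        rows <- sample.int(n_tr, n_tr, replace = TRUE)
        fit <- fit_polynomial(tr[rows, , drop = FALSE], dg)
        predict(fit, te)
      }, numeric(nrow(te)))
      err <- mean(colMeans((preds - te$d)^2))
      mu <- rowMeans(preds)
      bias2 <- mean((mu - te$d)^2)
      variance <- mean(rowMeans((preds - mu)^2))
      data.frame(degree = dg, error = err, bias2 = bias2,
                 variance = variance)
    })
    curves <- do.call(rbind, curves)
    chosen <- curves$degree[which.min(curves$error)]
    list(chosen = chosen, curves = curves)
  })
}

# ---- S3 methods -----------------------------------------------------------

#' Predict pairwise distances from a fitted surface model
#'
#' @param object a `beta_surface` model.
#' @param newdata data.frame (or matrix) with columns `g1` and `g2`.
#' @param ... unused.
#' @return numeric vector of predicted distances.
#' @export
predict.beta_surface <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    newdata <- data.frame(g1 = newdata[, 1], g2 = newdata[, 2])
  }
  X <- cbind(g1 = newdata$g1, g2 = newdata$g2)
  switch(object$method,
    gbt = as.numeric(.predict_ensemble_cpp(
      object$trees, X, rep(object$learning_rate, length(object$trees)),
      object$base_score)),
    random_forest = as.numeric(.predict_ensemble_cpp(
      object$trees, X, rep(1 / object$n_trees, object$n_trees), 0)),
    ffnn = {
      Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
      as.numeric(ffnn_forward(object$layers, Xs)[[length(object$layers) + 1]])
    },
    polynomial = as.numeric(
      poly_design(X[, 1], X[, 2], object$degree) %*% object$coefficients))
}

#' @export
fitted.beta_surface <- function(object, ...) object$fitted_values

#' @export
residuals.beta_surface <- function(object, ...) {
  object$train$d - object$fitted_values
}

#' @export
coef.polynomial_surface <- function(object, ...) object$coefficients

#' @export
print.beta_surface <- function(x, ...) {
  cat(sprintf("Beta-diversity surface model (%s), %d training pairs\n",
              x$method, nrow(x$train)))
  cat(sprintf("  training MSE %.4g\n", mean(residuals(x)^2)))
  invisible(x)
}

#' @export
summary.beta_surface <- function(object, ...) {
  res <- residuals(object)
  y <- object$train$d
  out <- list(method = object$method, n = nrow(object$train),
              train_mse = mean(res^2),
              train_r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
  class(out) <- "summary.beta_surface"
  out
}

#' @export
print.summary.beta_surface <- function(x, ...) {
  cat(sprintf("%s surface: n = %d, train MSE = %.4g, train R^2 = %.3f\n",
              x$method, x$n, x$train_mse, x$train_r2))
  invisible(x)
}

#' Predict the fitted surface over a meshgrid
#'
#' Builds a shared axis from the minimum to the maximum gradient value with
#' step equal to the smallest positive pairwise difference — capped so the
#' axis has at most `max_grid` points (the step is inflated accordingly,
#' with a warning), because the step rule is unbounded for near-duplicate
#' gradient values. Because a pairwise dissimilarity is symmetric by
#' definition, the surface cell `[u, v]` is the model prediction averaged
#' over both argument orders, `(f(g_u, g_v) + f(g_v, g_u))/2` (greedy tree
#' ensembles otherwise break exchange symmetry through deterministic
#' tie-breaking); the baseline is the mean over off-diagonal cells.
#'
#' @param model a fitted `beta_surface`.
#' @param gradient the per-site browning values (>= 2 distinct).
#' @param max_grid axis-length cap (default 500).
#' @return object of class `mesh_surface`: `axis`, `values` (matrix),
#'   `step`, `baseline`, `method`.
#' @export
predict_meshgrid <- function(model, gradient, max_grid = 500) {
  gs <- sort(unique(gradient))
  if (length(gs) < 2) {
    stop_bb("all gradient values identical", class = "degenerate_gradient")
  }
  step <- min(diff(gs))
  span <- max(gs) - min(gs)
  n_axis <- floor(span / step + 1e-9) + 1
  if (n_axis > max_grid) {
    step <- span / (max_grid - 1)
    n_axis <- max_grid
    warning(sprintf("meshgrid capped at %d points per axis (step inflated to %.4g)",
                    max_grid, step))
  }
  axis <- min(gs) + step * (seq_len(n_axis) - 1)
  grid <- expand.grid(g1 = axis, g2 = axis)
  pred <- predict(model, grid)
  values <- matrix(pred, n_axis, n_axis)
  values <- (values + t(values)) / 2
  off <- values
  diag(off) <- NA
  structure(list(axis = axis, values = values, step = step,
                 baseline = mean(off, na.rm = TRUE),
                 method = model$method),
            class = "mesh_surface")
}

#' @export
print.mesh_surface <- function(x, ...) {
  cat(sprintf("Mesh surface (%s): %d x %d, step %.4g, baseline %.4f\n",
              x$method, length(x$axis), length(x$axis), x$step, x$baseline))
  invisible(x)
}

#' @export
plot.mesh_surface <- function(x, ...,
                              xlab = "browning (site 1)",
                              ylab = "browning (site 2)",
                              main = sprintf("%s response surface", x$method)) {
  graphics::image(x$axis, x$axis, x$values, xlab = xlab, ylab = ylab,
                  main = main, useRaster = TRUE, ...)
  graphics::abline(0, 1, lty = 2)
}

#' @export
plot.beta_surface <- function(x, gradient = NULL, ...) {
  if (is.null(gradient)) gradient <- unique(c(x$train$g1, x$train$g2))
  plot(predict_meshgrid(x, gradient), ...)
}

#' Train/test error of a fitted surface model
#'
#' Mean-squared error and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, where `SS_tot` uses the evaluated fold's
#' own mean and the raw (unstandardised) targets. A zero-variance test
#' target leaves R^2 undefined (`NA` with a warning); the MSE is still
#' returned.
#'
#' @param model a fitted `beta_surface`.
#' @param test held-out pairs.
#' @return list of class `fit_metrics`: `train_mse`, `train_r2`,
#'   `test_mse`, `test_r2`.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) == 0) stop_bb("test set is empty", class = "invalid_input")
  r2_of <- function(y, pred) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) {
      warning("zero-variance target: R^2 undefined")
      return(NA_real_)
    }
    1 - sum((y - pred)^2) / ss_tot
  }
  tr_y <- model$train$d
  tr_pred <- model$fitted_values
  te_pred <- predict(model, test)
  structure(list(train_mse = mean((tr_y - tr_pred)^2),
                 train_r2 = r2_of(tr_y, tr_pred),
                 test_mse = mean((test$d - te_pred)^2),
                 test_r2 = r2_of(test$d, te_pred),
                 method = model$method),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("%s: train MSE %.4g / R^2 %.3f | test MSE %.4g / R^2 %.3f\n",
              x$method, x$train_mse, x$train_r2, x$test_mse, x$test_r2))
  invisible(x)
}
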