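# Shared fixtures and independent oracles, all built in code.

tiny_counts <- function() {
  m <- rbind(a = c(5L, 3L, 0L, 2L),
             b = c(1L, 0L, 4L, 5L),
             c = c(0L, 2L, 2L, 6L))
  colnames(m) <- paste0("t", 1:4)
  m
}

random_counts <- function(n_sites, n_taxa, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_sites * n_taxa, lambda), n_sites, n_taxa)
    rownames(m) <- paste0("s", seq_len(n_sites))
    colnames(m) <- paste0("t", seq_len(n_taxa))
    m
  })
}

# small, fast synthetic scenario for structural tests
small_scenario <- function(seed = 1) {
  simulate_browning_dataset(n_sites = 40, n_taxa = 60, depth = 2000,
                            seed = seed)
}

# turnover-profile object built by hand (for detector unit tests)
make_profile <- function(g, t, surface_baseline = mean(t), band_k = 3) {
  structure(data.frame(g = g, t = t),
            class = c("turnover_profile", "data.frame"),
            baseline = surface_baseline, band_k = band_k)
}

# mesh_surface built by hand
make_surface <- function(axis, values) {
  off <- values
  diag(off) <- NA
  structure(list(axis = axis, values = values,
                 step = axis[2] - axis[1],
                 baseline = mean(off, na.rm = TRUE), method = "test"),
            class = "mesh_surface")
}

# Hand Bray-Curtis for oracle use
bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Mutual information (bits) of a contingency table — oracle building block
mi_bits <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# Exhaustive best clump-respecting x-partition into exactly <= l columns.
# clumps: integer clump id per point (nondecreasing along sorted x).
brute_best_mi <- function(x, row, l, clump_factor = 1e6) {
  cid <- betabrowning:::.clump_ids_cpp(x, row, as.integer(clump_factor))
  ord <- order(x)
  cid_s <- cid[ord]
  row_s <- row[ord]
  k <- max(cid_s)
  if (k < 2) return(0)
  bounds <- 1:(k - 1)  # split after clump b
  best <- 0
  for (nb in 1:min(l - 1, k - 1)) {
    combs <- utils::combn(bounds, nb, simplify = FALSE)
    for (cb in combs) {
      col <- findInterval(cid_s, c(cb + 0.5)) + 1L
      tab <- table(col, row_s)
      best <- max(best, mi_bits(tab))
    }
  }
  best
}

# linear pairwise-distance toy: d = a + b (g1 + g2) + noise, clipped to [0,1]
linear_pair_scenario <- function(n_sites = 60, noise_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    g <- runif(n_sites, 0, 12)
    d <- outer(g, g, function(u, v) 0.3 + 0.02 * (u + v)) +
      matrix(rnorm(n_sites^2, 0, noise_sd), n_sites)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d <- pmin(pmax(d, 0), 1)
    list(g = g, d = d)
  })
}

# regime-free monotone scenario (false-positive control)
monotone_scenario <- function(seed) {
  simulate_browning_dataset(thresholds = numeric(0), n_alt_states = 1,
                            convergence_threshold = Inf,
                            shape_mix = c(0.5, 0.5, 0, 0), seed = seed)
}

# run the full threshold pipeline on a dataset, return non-edge ridges
pipeline_ridges <- function(ds) {
  g <- ds$site_table$gradient_value
  fit <- fit_gradient_boost(build_pair_dataset(g, bray_curtis(ds$counts)))
  surf <- suppressWarnings(predict_meshgrid(fit, g))
  rep <- detect_ridges_valleys(turnover_profile(surf))
  rep$ridges[!rep$ridges$edge, , drop = FALSE]
}
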