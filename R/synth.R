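#' Simulate a per-site browning gradient
#'
#' Draws the browning descriptor (e.g. TOC in mg C per litre, or a_CDOM in
#' absorbance units) for a set of sites, either uniformly at random across
#' the bounds or as an equally spaced sequence including both bounds.
#'
#' @param n_sites number of sites (>= 2).
#' @param g_min,g_max gradient bounds, `g_min < g_max`.
#' @param spacing `"uniform_random"` or `"equally_spaced"`.
#' @param seed optional integer seed; identical seeds give identical values.
#' @return numeric vector of length `n_sites`, all values in
#'   `[g_min, g_max]`.
#' @examples
#' make_gradient(5, 0.3, 12.9, "equally_spaced")
#' @export
make_gradient <- function(n_sites, g_min, g_max,
                          spacing = c("uniform_random", "equally_spaced"),
                          seed = NULL) {
  spacing <- match.arg(spacing)
  if (!is.numeric(n_sites) || n_sites < 2) {
    stop_bb("n_sites must be >= 2 (got %s)", n_sites, class = "invalid_design")
  }
  if (g_min >= g_max) {
    stop_bb("g_min (%g) must be strictly below g_max (%g)", g_min, g_max,
            class = "invalid_design")
  }
  if (spacing == "equally_spaced") {
    return(seq(g_min, g_max, length.out = n_sites))
  }
  with_seed(seed, runif(n_sites, g_min, g_max))
}

#' Describe a regime structure along the gradient
#'
#' A regime model places community-shift thresholds (tau) inside the
#' gradient, allows several alternative community states to coexist below a
#' convergence level, and reserves a block of indicator taxa per state.
#'
#' @param thresholds strictly increasing tau values (may be empty).
#' @param n_alt_states number of alternative states per low-browning segment.
#' @param convergence_threshold gradient value above which a single state
#'   exists; must be `>=` every threshold.
#' @param state_taxa_per_regime indicator taxa reserved for each state.
#' @return a `regime_model` list.
#' @export
regime_model <- function(thresholds = numeric(0), n_alt_states = 2L,
                         convergence_threshold = Inf,
                         state_taxa_per_regime = 8L) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) && any(diff(thresholds) <= 0)) {
    stop_bb("thresholds must be strictly increasing",
            class = "invalid_regime")
  }
  if (n_alt_states < 1) {
    stop_bb("n_alt_states must be >= 1", class = "invalid_regime")
  }
  if (length(thresholds) && convergence_threshold < max(thresholds)) {
    stop_bb("convergence_threshold must be >= max(thresholds)",
            class = "invalid_regime")
  }
  structure(list(thresholds = thresholds,
                 n_alt_states = as.integer(n_alt_states),
                 convergence_threshold = convergence_threshold,
                 state_taxa_per_regime = as.integer(state_taxa_per_regime)),
            class = "regime_model")
}

#' Draw a catalogue of per-taxon gradient responses
#'
#' Each taxon gets one of four expected-abundance response shapes over the
#' gradient: logistic increase (`monotone_up`), logistic decrease
#' (`monotone_down`), Gaussian (`unimodal`, optimum drawn with a Beta(2, 2)
#' density peaked mid-gradient so realised richness humps at intermediate
#' browning), or a sharp logistic `step` located at one of the regime
#' thresholds (width 1% of the gradient range, a differentiable stand-in for
#' a discontinuity).
#'
#' The catalogue mirrors the structure of lake bacterioplankton along a
#' browning gradient: monotone taxa are abundant generalists with broad,
#' slow responses (widths of a third to two-thirds of the range), so that
#' community dissimilarity between distant sites is dominated by regime
#' structure rather than by smooth gradient turnover; unimodal taxa are
#' narrow-niche specialists with an order of magnitude lower amplitude —
#' they shape presence/absence richness but carry little weight in
#' abundance-based Bray-Curtis distances.
#'
#' @param n_taxa number of gradient-response taxa.
#' @param shape_mix nonnegative proportions over the four shapes, in the
#'   order `monotone_up`, `monotone_down`, `unimodal`, `step`; must sum to 1.
#' @param g_min,g_max gradient bounds the responses live on.
#' @param regime a [regime_model()]; required when the step proportion is
#'   positive (step locations are drawn from its thresholds).
#' @param seed optional integer seed.
#' @return data.frame with columns `taxon`, `shape`, `location`, `width`,
#'   `amplitude`, `direction`.
#' @export
make_taxon_responses <- function(n_taxa, shape_mix, g_min, g_max,
                                 regime = NULL, seed = NULL) {
  shapes <- c("monotone_up", "monotone_down", "unimodal", "step")
  if (!is.null(names(shape_mix))) shape_mix <- shape_mix[shapes]
  shape_mix <- as.numeric(shape_mix)
  if (length(shape_mix) != 4 || any(is.na(shape_mix)) || any(shape_mix < 0) ||
      abs(sum(shape_mix) - 1) > 1e-9) {
    stop_bb("shape_mix must be 4 nonnegative proportions summing to 1",
            class = "invalid_mix")
  }
  counts <- apportion(n_taxa, shape_mix)
  if (counts[4] > 0 && (is.null(regime) || !length(regime$thresholds))) {
    stop_bb("step taxa requested but regime has no thresholds",
            class = "invalid_mix")
  }
  R <- g_max - g_min
  with_seed(seed, {
    shape <- rep(shapes, counts)
    n <- length(shape)
    location <- numeric(n)
    width <- numeric(n)
    direction <- rep(1, n)
    amplitude <- numeric(n)
    mono <- shape %in% c("monotone_up", "monotone_down")
    location[mono] <- runif(sum(mono), g_min + 0.1 * R, g_max - 0.1 * R)
    width[mono] <- runif(sum(mono), R / 2, R)
    amplitude[mono] <- rlnorm(sum(mono), 0, 1)
    uni <- shape == "unimodal"
    location[uni] <- g_min + R * rbeta(sum(uni), 2, 2)
    width[uni] <- runif(sum(uni), R / 10, R / 4)
    amplitude[uni] <- rlnorm(sum(uni), -1.5, 0.7)
    stp <- shape == "step"
    if (any(stp)) {
      location[stp] <- sample(regime$thresholds, sum(stp), replace = TRUE)
      width[stp] <- 0.01 * R
      direction[stp] <- sample(c(-1, 1), sum(stp), replace = TRUE)
      amplitude[stp] <- rlnorm(sum(stp), 0, 1)
    }
    data.frame(taxon = paste0("taxon", seq_len(n)), shape = shape,
               location = location, width = width,
               amplitude = amplitude, direction = direction,
               stringsAsFactors = FALSE)
  })
}

# Expected (unnormalised) abundance of every response taxon at every g.
response_matrix <- function(responses, g) {
  n <- length(g)
  out <- matrix(0, n, nrow(responses),
                dimnames = list(NULL, responses$taxon))
  for (j in seq_len(nrow(responses))) {
    r <- responses[j, ]
    out[, j] <- switch(r$shape,
      monotone_up   = r$amplitude * plogis((g - r$location) / r$width),
      monotone_down = r$amplitude * plogis(-(g - r$location) / r$width),
      unimodal      = r$amplitude * exp(-(g - r$location)^2 / (2 * r$width^2)),
      step          = r$amplitude *
                        plogis(r$direction * (g - r$location) / r$width))
  }
  out
}

#' Assign each site to a community state
#'
#' Sites at or above the convergence threshold all share the single
#' `"converged"` state. Sites below are placed in the segment delimited by
#' the regime thresholds and assigned uniformly at random (seeded) to one of
#' the segment's alternative states.
#'
#' @param g per-site gradient values.
#' @param regime a [regime_model()].
#' @param seed optional integer seed.
#' @return character vector of state ids (e.g. `"s1_a2"`, `"converged"`).
#' @export
assign_states <- function(g, regime, seed = NULL) {
  if (!inherits(regime, "regime_model")) {
    stop_bb("regime must be a regime_model", class = "invalid_regime")
  }
  low_thr <- regime$thresholds[regime$thresholds < regime$convergence_threshold]
  seg <- findInterval(g, low_thr) + 1L
  with_seed(seed, {
    state <- character(length(g))
    conv <- g >= regime$convergence_threshold
    state[conv] <- "converged"
    for (s in unique(seg[!conv])) {
      i <- which(!conv & seg == s)
      state[i] <- paste0("s", s, "_a",
                         sample.int(regime$n_alt_states, length(i),
                                    replace = TRUE))
    }
    state
  })
}

#' Expected relative-abundance profiles per site
#'
#' Combines the gradient-response taxa with per-state indicator taxa. Each
#' site's indicator block receives a fixed fraction (`state_fraction`) of its
#' total expected abundance, split equally across the taxa of its own state;
#' indicator taxa of other states get zero. Rows are normalised to sum to 1.
#'
#' @param g per-site gradient values.
#' @param states per-site state ids from [assign_states()].
#' @param responses response catalogue from [make_taxon_responses()].
#' @param regime a [regime_model()].
#' @param state_fraction share of expected relative abundance carried by the
#'   state-indicator taxa (default 0.5, the top of the 0.3-0.5 band that keeps
#'   thresholds detectable but not trivial).
#' @return matrix of per-site probability vectors (rows sum to 1).
#' @export
expected_profiles <- function(g, states, responses, regime,
                              state_fraction = 0.5) {
  if (length(states) != length(g)) {
    stop_bb("g and states lengths differ", class = "invalid_profile")
  }
  G <- response_matrix(responses, g)
  rowG <- rowSums(G)
  if (any(rowG <= 0)) {
    stop_bb("site %d has zero total expected abundance",
            which(rowG <= 0)[1], class = "degenerate_profile")
  }
  ids <- sort(unique(states))
  per <- regime$state_taxa_per_regime
  if (per > 0) {
    S <- matrix(0, length(g), length(ids) * per,
                dimnames = list(NULL,
                                paste0(rep(ids, each = per), "_ind",
                                       rep(seq_len(per), length(ids)))))
    total_state <- rowG * state_fraction / (1 - state_fraction)
    for (k in seq_along(ids)) {
      i <- which(states == ids[k])
      cols <- (k - 1) * per + seq_len(per)
      S[i, cols] <- total_state[i] / per
    }
    out <- cbind(G, S)
  } else {
    out <- G
  }
  out / rowSums(out)
}

#' Multinomial read sampling of expected profiles
#'
#' @param profiles per-site probability vectors (rows sum to 1).
#' @param depth reads per site (constant across sites).
#' @param seed optional integer seed.
#' @return integer count matrix; every row sums to exactly `depth`.
#' @export
sample_counts <- function(profiles, depth = 10000, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) {
    stop_bb("profiles contain negative probabilities",
            class = "invalid_profile")
  }
  if (depth < 1) stop_bb("depth must be >= 1", class = "invalid_profile")
  with_seed(seed, {
    out <- t(apply(profiles, 1, function(p) {
      rmultinom(1, size = depth, prob = p)[, 1]
    }))
    colnames(out) <- colnames(profiles)
    rownames(out) <- paste0("site", seq_len(nrow(out)))
    storage.mode(out) <- "integer"
    out
  })
}

#' Simulate CDOM-like absorption spectra
#'
#' Noiseless absorption follows the standard exponential model
#' `a(lambda) = a400(g) * exp(-S_decay * (lambda - 400))` over 400-750 nm at
#' 1-nm steps, with `a400` increasing linearly in the browning value g.
#' Gaussian noise is added and clipped at a small positive floor so spectra
#' stay strictly positive for downstream log/PCA stages.
#'
#' @param g per-site gradient values.
#' @param a400_slope increase of a400 per gradient unit (m^-1 per unit g).
#' @param S_decay spectral decay slope (nm^-1), > 0.
#' @param noise_sd additive Gaussian noise s.d. (0 for noiseless spectra).
#' @param seed optional integer seed.
#' @param a400_intercept a400 at g = 0 (m^-1).
#' @param floor clip level for noise-driven negative absorbances.
#' @return matrix with 351 wavelength columns named `"400"`..`"750"`.
#' @export
make_spectra <- function(g, a400_slope = 0.2, S_decay = 0.018,
                         noise_sd = 0.01, seed = NULL,
                         a400_intercept = 0.05, floor = 1e-6) {
  if (S_decay <= 0) stop_bb("S_decay must be > 0", class = "invalid_spectra")
  lambda <- 400:750
  a400 <- a400_intercept + a400_slope * g
  base <- outer(a400, exp(-S_decay * (lambda - 400)))
  out <- with_seed(seed, {
    base + if (noise_sd > 0) {
      matrix(rnorm(length(base), 0, noise_sd), nrow(base))
    } else 0
  })
  out <- pmax(out, floor)
  dimnames(out) <- list(paste0("site", seq_along(g)), as.character(lambda))
  out
}

#' Simulate a complete synthetic browning dataset
#'
#' The default arguments are the standard synthetic scenario used throughout
#' the package's validation: 80 sites on a 0-12 browning gradient, 300
#' gradient-response taxa, regime thresholds at tau = 3 and 7 with 2
#' alternative states below the convergence level of 7, and a constant
#' multinomial depth of 10,000 reads per site.
#'
#' @param n_sites,n_taxa,g_min,g_max,spacing passed to [make_gradient()] and
#'   [make_taxon_responses()].
#' @param thresholds,n_alt_states,convergence_threshold,state_taxa_per_regime
#'   passed to [regime_model()].
#' @param shape_mix response-shape proportions (up, down, unimodal, step).
#' @param state_fraction see [expected_profiles()].
#' @param depth reads per site.
#' @param spectra_noise_sd spectral noise s.d. (see [make_spectra()]).
#' @param seed integer seed; sub-stage seeds are derived as `seed * 10 + k`
#'   for stage k so stage-level reruns stay reproducible.
#' @return a `browning_dataset` list with elements `counts`, `site_table`
#'   (site_id, gradient_value, state_id, depth), `spectra` and `truth`
#'   (thresholds, convergence threshold, response catalogue, states).
#' @export
simulate_browning_dataset <- function(n_sites = 80, n_taxa = 300,
                                      g_min = 0, g_max = 12,
                                      spacing = "uniform_random",
                                      thresholds = c(3, 7),
                                      n_alt_states = 2,
                                      convergence_threshold = 7,
                                      state_taxa_per_regime = 8,
                                      shape_mix = c(monotone_up = 0.2,
                                                    monotone_down = 0.2,
                                                    unimodal = 0.5,
                                                    step = 0.1),
                                      state_fraction = 0.5,
                                      depth = 10000,
                                      spectra_noise_sd = 0.01,
                                      seed = 1) {
  regime <- regime_model(thresholds, n_alt_states, convergence_threshold,
                         state_taxa_per_regime)
  g <- make_gradient(n_sites, g_min, g_max, spacing, seed = seed * 10 + 1)
  responses <- make_taxon_responses(n_taxa, shape_mix, g_min, g_max, regime,
                                    seed = seed * 10 + 2)
  states <- assign_states(g, regime, seed = seed * 10 + 3)
  profiles <- expected_profiles(g, states, responses, regime, state_fraction)
  counts <- sample_counts(profiles, depth, seed = seed * 10 + 4)
  spectra <- make_spectra(g, noise_sd = spectra_noise_sd,
                          seed = seed * 10 + 5)
  site_table <- data.frame(site_id = rownames(counts), gradient_value = g,
                           state_id = states, depth = depth,
                           stringsAsFactors = FALSE)
  truth <- list(thresholds = regime$thresholds,
                convergence_threshold = regime$convergence_threshold,
                responses = responses,
                states = stats::setNames(states, site_table$site_id),
                state_fraction = state_fraction,
                g_min = g_min, g_max = g_max)
  structure(list(counts = counts, site_table = site_table,
                 spectra = spectra, truth = truth, profiles = profiles),
            class = "browning_dataset")
}

#' @export
print.browning_dataset <- function(x, ...) {
  cat("Synthetic browning dataset:", nrow(x$counts), "sites x",
      ncol(x$counts), "taxa\n")
  cat("  gradient:", format(range(x$site_table$gradient_value), digits = 3),
      " thresholds:", paste(x$truth$thresholds, collapse = ", "), "\n")
  invisible(x)
}

fmt_num <- function(m) {
  # full-precision text so the TSV round trip is bit-exact
  matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
}

#' Write / read a synthetic dataset as plain-text files
#'
#' Writes `counts.tsv` (first column `site_id`), `site_metadata.tsv`,
#' `spectra.tsv` and `truth.json` into `dir`. [read_dataset()] reproduces
#' the matrices cell-for-cell and the ground truth losslessly.
#'
#' @param dataset a `browning_dataset`.
#' @param dir an existing, writable directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    stop_bb("directory does not exist: %s", dir, class = "io_error")
  }
  wr <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(data.frame(site_id = rownames(dataset$counts), dataset$counts,
                check.names = FALSE), "counts.tsv")
  meta <- dataset$site_table
  meta$gradient_value <- sprintf("%.17g", meta$gradient_value)
  wr(meta, "site_metadata.tsv")
  wr(data.frame(site_id = rownames(dataset$spectra),
                fmt_num(dataset$spectra), check.names = FALSE),
     "spectra.tsv")
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(file) {
    f <- file.path(dir, file)
    if (!file.exists(f)) stop_bb("missing file: %s", f, class = "io_error")
    read.table(f, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  cts <- rd("counts.tsv")
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$site_id
  storage.mode(counts) <- "integer"
  meta <- rd("site_metadata.tsv")
  sp <- rd("spectra.tsv")
  spectra <- as.matrix(sp[, -1, drop = FALSE])
  rownames(spectra) <- sp$site_id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$thresholds <- as.numeric(truth$thresholds)
  truth$states <- unlist(truth$states)
  truth$responses <- as.data.frame(truth$responses,
                                   stringsAsFactors = FALSE)
  structure(list(counts = counts, site_table = meta, spectra = spectra,
                 truth = truth), class = "browning_dataset")
}
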