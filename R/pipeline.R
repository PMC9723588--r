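#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Simulation keys
#' default to the standard synthetic scenario; alternatively `counts_tsv`
#' and `metadata_tsv` point at existing data (with `gradient_column`
#' naming the browning descriptor). Unknown keys are rejected at
#' validation time.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "alpha", "mine", "surface", "thresholds",
               "varpart"),
    counts_tsv = NULL, metadata_tsv = NULL, spectra_tsv = NULL,
    gradient_column = "gradient_value",
    n_sites = 80L, n_taxa = 300L, g_min = 0, g_max = 12,
    thresholds = c(3, 7), n_alt_states = 2L, convergence_threshold = 7,
    state_taxa_per_regime = 8L, state_fraction = 0.45, depth = 10000L,
    mine_n_perm = 199L, mine_mic_cutoff = 0.3, mine_mas_cutoff = 0.05,
    mine_fdr_level = 0.05, mine_max_taxa = 50L,
    surface_method = "gbt", gbt_rounds = 300L, gbt_depth = 3L,
    gbt_learning_rate = 0.1, gbt_lambda = 1, train_frac = 0.8,
    band_k = 3L, min_prominence_frac = 0.1, min_separation_frac = 0.05,
    max_grid = 500L
  )
}

# stage seeds fan out from the global seed by a fixed affine hash
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483647L

#' Run the simulate - metrics - MINE - surface - thresholds - varpart
#' pipeline
#'
#' Executes the requested stages in dependency order, writing every
#' artifact as TSV/JSON into `outdir` together with a run manifest
#' (stage outputs, seeds, timings, and every default that filled an
#' omitted config key). Identical config and seed give byte-identical
#' outputs. A stage failure aborts with the failing stage named and
#' leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config named list overriding [default_config()] keys; unknown
#'   keys are an error.
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_bb("unknown config keys: %s", paste(unknown, collapse = ", "),
            class = "invalid_config")
  }
  filled <- setdiff(names(defaults), names(config))
  cfg <- utils::modifyList(defaults, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", "betabrowning", sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  manifest <- list(config = cfg[order(names(cfg))],
                   defaults_filled = sort(filled),
                   seed = cfg$seed, stages = list())
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop_bb("pipeline stage '%s' failed: %s", name, conditionMessage(e),
              class = "stage_error")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = res)
    logmsg("stage %s done (%.1fs)", name,
           manifest$stages[[name]]$seconds)
    invisible(res)
  }

  env <- new.env()
  wr_tsv <- function(df, file) {
    write.table(df, file.path(outdir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
    file
  }
  wr_json <- function(x, file) {
    jsonlite::write_json(x, file.path(outdir, file), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    file
  }

  run_stage("simulate", function() {
    if (!is.null(cfg$counts_tsv)) {
      cts <- read.table(cfg$counts_tsv, header = TRUE, sep = "\t",
                        check.names = FALSE)
      env$counts <- as.matrix(cts[, -1])
      rownames(env$counts) <- cts[[1]]
      env$meta <- read.table(cfg$metadata_tsv, header = TRUE, sep = "\t",
                             check.names = FALSE)
      env$g <- env$meta[[cfg$gradient_column]]
      if (!is.null(cfg$spectra_tsv)) {
        sp <- read.table(cfg$spectra_tsv, header = TRUE, sep = "\t",
                         check.names = FALSE)
        env$spectra <- as.matrix(sp[, -1])
      }
      return(list(loaded = cfg$counts_tsv))
    }
    ds <- simulate_browning_dataset(
      n_sites = cfg$n_sites, n_taxa = cfg$n_taxa, g_min = cfg$g_min,
      g_max = cfg$g_max, thresholds = cfg$thresholds,
      n_alt_states = cfg$n_alt_states,
      convergence_threshold = cfg$convergence_threshold,
      state_taxa_per_regime = cfg$state_taxa_per_regime,
      state_fraction = cfg$state_fraction, depth = cfg$depth,
      seed = stage_seed(cfg$seed, 1L))
    datadir <- file.path(outdir, "data")
    dir.create(datadir, showWarnings = FALSE)
    write_dataset(ds, datadir)
    env$counts <- ds$counts
    env$meta <- ds$site_table
    env$g <- ds$site_table$gradient_value
    env$spectra <- ds$spectra
    env$truth <- ds$truth
    list(dir = "data")
  })

  run_stage("alpha", function() {
    al <- alpha_diversity(env$counts,
                          c("richness", "shannon", "simpson", "inv_simpson"))
    hump <- alpha_hump_test(al$richness, env$g)
    list(alpha = wr_tsv(cbind(site_id = rownames(al), al), "alpha.tsv"),
         hump = wr_json(list(winner = hump$winner, peak = hump$peak,
                             aic_linear = hump$aic_linear,
                             aic_quadratic = hump$aic_quadratic),
                        "alpha_hump.json"))
  })

  run_stage("mine", function() {
    counts <- env$counts
    if (!is.null(cfg$mine_max_taxa) && ncol(counts) > cfg$mine_max_taxa) {
      rel <- counts / rowSums(counts)
      keep <- order(apply(rel, 2, var), decreasing = TRUE)[
        seq_len(cfg$mine_max_taxa)]
      counts <- counts[, sort(keep), drop = FALSE]
    }
    mc <- mine_config(n_perm = cfg$mine_n_perm,
                      mic_cutoff = cfg$mine_mic_cutoff,
                      mas_monotone_cutoff = cfg$mine_mas_cutoff,
                      fdr_level = cfg$mine_fdr_level,
                      seed = stage_seed(cfg$seed, 3L))
    res <- mine_screen(counts, env$g, mc)
    env$mine <- res
    list(results = wr_tsv(res, "mine_results.tsv"))
  })

  run_stage("surface", function() {
    d <- bray_curtis(env$counts)
    pairs <- build_pair_dataset(env$g, d)
    folds <- split_train_test(pairs, cfg$train_frac,
                              seed = stage_seed(cfg$seed, 4L))
    model <- switch(cfg$surface_method,
      gbt = fit_gradient_boost(folds$train, cfg$gbt_rounds, cfg$gbt_depth,
                               cfg$gbt_learning_rate, cfg$gbt_lambda),
      random_forest = fit_random_forest(folds$train,
                                        seed = stage_seed(cfg$seed, 4L)),
      polynomial = fit_polynomial(folds$train, degree = 3),
      ffnn = fit_ffnn(folds$train, seed = stage_seed(cfg$seed, 4L)),
      stop_bb("unknown surface_method '%s'", cfg$surface_method,
              class = "invalid_config"))
    metrics <- evaluate_model(model, folds$test)
    env$surface <- predict_meshgrid(model, env$g, cfg$max_grid)
    surf_df <- data.frame(g = env$surface$axis, env$surface$values,
                          check.names = FALSE)
    colnames(surf_df) <- c("g", sprintf("%.17g", env$surface$axis))
    list(surface = wr_tsv(surf_df, "surface.tsv"),
         metrics = wr_json(list(method = cfg$surface_method,
                                train_mse = metrics$train_mse,
                                test_mse = metrics$test_mse,
                                train_r2 = metrics$train_r2,
                                test_r2 = metrics$test_r2,
                                baseline = env$surface$baseline,
                                hyperparameters = list(
                                  rounds = cfg$gbt_rounds,
                                  depth = cfg$gbt_depth,
                                  learning_rate = cfg$gbt_learning_rate,
                                  lambda = cfg$gbt_lambda)),
                           "surface_metrics.json"))
  })

  run_stage("thresholds", function() {
    if (is.null(env$surface)) {
      stop_bb("thresholds stage requires the surface stage",
              class = "invalid_config")
    }
    prof <- turnover_profile(env$surface, cfg$band_k)
    rep <- detect_ridges_valleys(prof,
                                 min_prominence_frac = cfg$min_prominence_frac,
                                 min_separation_frac = cfg$min_separation_frac)
    gs <- guardrail_summary(list(gradient = rep))
    list(profile = wr_tsv(prof, "turnover_profile.tsv"),
         thresholds = wr_json(list(
           descriptor = cfg$gradient_column,
           ridges = rep$ridges, valleys = rep$valleys,
           baseline = rep$baseline, params = rep$params,
           regimes = gs$gradient$regimes), "thresholds.json"))
  })

  run_stage("varpart", function() {
    if (is.null(env$spectra)) {
      stop_bb("varpart stage requires spectra", class = "invalid_config")
    }
    hel <- hellinger_transform(env$counts)
    pca <- cdom_pca_index(env$spectra)
    vp <- variance_partition(hel, list(
      browning = matrix(env$g, dimnames = list(NULL, "g")),
      cdom = matrix(pca$scores[, 1], dimnames = list(NULL, "pc1"))))
    list(varpart = wr_json(list(fractions = as.list(vp$fractions),
                                residual = vp$residual,
                                pc1_percent = pca$pc1_percent),
                           "varpart.json"))
  })

  manifest$package_version <- as.character(utils::packageVersion("betabrowning"))
  wr_json(manifest, "manifest.json")
  logmsg("pipeline complete: %d stages", length(manifest$stages))
  invisible(manifest)
}
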