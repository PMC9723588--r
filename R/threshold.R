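#' Near-diagonal community turnover profile
#'
#' Reads the fitted response surface next to its diagonal: at axis position
#' `u`, the turnover `t(g_u)` is the mean predicted distance over cells
#' `[u, v]` with `0 < |u - v| <= band_k`. Endpoints use the available
#' one-sided band. This formalises reading "a point bordering the diagonal"
#' off the surface.
#'
#' @param surface a [predict_meshgrid()] result.
#' @param band_k band half-width in grid steps (default 3).
#' @return data.frame of class `turnover_profile` with columns `g` and `t`;
#'   carries the surface baseline as attribute `"baseline"`.
#' @export
turnover_profile <- function(surface, band_k = 3) {
  n <- length(surface$axis)
  if (band_k < 1 || band_k >= n) {
    stop_bb("band_k must be in [1, axis length)", class = "invalid_band")
  }
  if (n <= 2 * band_k) {
    stop_bb("axis length (%d) must exceed 2 * band_k", n,
            class = "invalid_band")
  }
  t_val <- vapply(seq_len(n), function(u) {
    v <- setdiff(max(1, u - band_k):min(n, u + band_k), u)
    mean(surface$values[u, v])
  }, numeric(1))
  structure(data.frame(g = surface$axis, t = t_val),
            class = c("turnover_profile", "data.frame"),
            baseline = surface$baseline, band_k = band_k)
}

# prominence of a local extremum: height above the higher of the two
# minima reached before a taller point (classic peak prominence on t)
peak_prominence <- function(t, i) {
  n <- length(t)
  side_min <- function(idx) {
    m <- t[i]
    for (j in idx) {
      if (t[j] > t[i]) break
      m <- min(m, t[j])
    }
    m
  }
  lm <- if (i > 1) side_min((i - 1):1) else t[i]
  rm <- if (i < n) side_min((i + 1):n) else t[i]
  t[i] - max(lm, rm)
}

#' Detect ridges and valleys of the turnover profile
#'
#' Ridges — thresholds ("guardrails") where the community shift exceeds the
#' baseline — are local maxima of the turnover profile with prominence at
#' least `min_prominence_frac` of the profile's range and a turnover above
#' the surface baseline. Valleys (stable regimes) are the analogous local
#' minima below the baseline. Features closer than `min_separation_frac`
#' of the gradient range are merged, keeping the more prominent one.
#' Extrema at the axis ends are reported but flagged `edge = TRUE`, since
#' their one-sided bands are less trustworthy. Prominence is relative, so
#' detection is invariant to rescaling of the surface (distances are
#' ratio-scale). A flat profile — range below `flat_tol` times the mesh
#' surface's baseline beta-diversity, i.e. near-diagonal community shift
#' essentially constant along the whole gradient on the scale of typical
#' between-site dissimilarity — yields an empty report rather than
#' promoting model noise to thresholds.
#'
#' @param profile a [turnover_profile()] result.
#' @param baseline reference level for the ridge/valley gate; defaults to
#'   the mean of the turnover profile itself (the average near-diagonal
#'   community shift), so ridges are positions shifting more than average
#'   and valleys less. The mesh surface's global mean stays available as
#'   `surface_baseline` in the report.
#' @param min_prominence_frac prominence floor as a fraction of
#'   `max(t) - min(t)` (default 0.1).
#' @param min_separation_frac merge radius as a fraction of the gradient
#'   range (default 0.05).
#' @param flat_tol flatness tolerance: if `max(t) - min(t)` is below
#'   `flat_tol` times the surface baseline (the mean predicted
#'   dissimilarity) the profile counts as flat (default 0.25).
#' @return list of class `threshold_report` with data.frames `ridges` and
#'   `valleys` (columns `position`, `prominence`, `edge`), the `baseline`,
#'   and the parameters used.
#' @export
detect_ridges_valleys <- function(profile, baseline = NULL,
                                  min_prominence_frac = 0.1,
                                  min_separation_frac = 0.05,
                                  flat_tol = 0.25) {
  if (nrow(profile) < 5) {
    stop_bb("profile needs >= 5 points", class = "invalid_band")
  }
  if (is.null(baseline)) baseline <- mean(profile$t)
  g <- profile$g
  t_val <- profile$t
  rng <- max(t_val) - min(t_val)
  flat_ref <- attr(profile, "baseline")
  if (is.null(flat_ref)) flat_ref <- baseline
  if (rng < flat_tol * flat_ref) rng <- 0  # flat profile: empty report
  min_sep <- min_separation_frac * (max(g) - min(g))
  empty <- data.frame(position = numeric(0), prominence = numeric(0),
                      edge = logical(0))

  find_features <- function(t, above) {
    n <- length(t)
    if (rng == 0) return(empty)
    # piecewise-constant model predictions give plateaus: collapse runs of
    # equal turnover and detect extrema over the runs
    runs <- rle(t)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    mids <- floor((starts + ends) / 2)
    rv <- runs$values
    m <- length(rv)
    if (m < 2) return(empty)
    is_max <- vapply(seq_len(m), function(j) {
      left <- if (j > 1) rv[j] > rv[j - 1] else TRUE
      right <- if (j < m) rv[j] > rv[j + 1] else TRUE
      left && right
    }, logical(1))
    cand_runs <- which(is_max)
    cand <- mids[cand_runs]
    if (!length(cand)) return(empty)
    prom <- vapply(cand_runs, function(j) peak_prominence(rv, j), numeric(1))
    keep <- prom >= min_prominence_frac * rng &
      (if (above) t_val[cand] > baseline else t_val[cand] < baseline)
    cand_runs <- cand_runs[keep]
    cand <- cand[keep]
    prom <- prom[keep]
    if (!length(cand)) return(empty)
    df <- data.frame(position = g[cand], prominence = prom,
                     edge = starts[cand_runs] == 1L | ends[cand_runs] == n)
    # merge close features, keeping the more prominent
    df <- df[order(-df$prominence), , drop = FALSE]
    kept <- df[0, ]
    for (r in seq_len(nrow(df))) {
      if (!nrow(kept) || all(abs(kept$position - df$position[r]) >= min_sep)) {
        kept <- rbind(kept, df[r, ])
      }
    }
    kept[order(kept$position), , drop = FALSE]
  }

  structure(list(ridges = find_features(t_val, above = TRUE),
                 valleys = find_features(-t_val, above = FALSE),
                 baseline = baseline,
                 surface_baseline = attr(profile, "baseline"),
                 params = list(min_prominence_frac = min_prominence_frac,
                               min_separation_frac = min_separation_frac,
                               flat_tol = flat_tol,
                               band_k = attr(profile, "band_k"),
                               gradient_range = range(g))),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  fmt <- function(df) {
    if (!nrow(df)) return("none")
    paste(sprintf("%.3g%s", df$position, ifelse(df$edge, "*", "")),
          collapse = ", ")
  }
  cat("Threshold report (baseline", sprintf("%.3f):\n", x$baseline))
  cat("  ridges :", fmt(x$ridges), "\n")
  cat("  valleys:", fmt(x$valleys), "\n")
  if (any(x$ridges$edge) || any(x$valleys$edge)) {
    cat("  (* = at axis edge; one-sided band)\n")
  }
  invisible(x)
}

#' Summarise guardrails and regimes across descriptors
#'
#' Orders each report's ridge positions and derives the inter-threshold
#' regime intervals that partition the gradient range; the result is a
#' plain list that serialises to JSON and round-trips through
#' [jsonlite::fromJSON()].
#'
#' @param reports named list of [detect_ridges_valleys()] reports, one per
#'   browning descriptor.
#' @return list of class `guardrail_summary`, one element per descriptor
#'   with `thresholds`, `valleys`, `regimes` (data.frame `from`/`to`) and
#'   `baseline`.
#' @export
guardrail_summary <- function(reports) {
  if (!length(reports)) stop_bb("need >= 1 report", class = "invalid_input")
  if (inherits(reports, "threshold_report")) {
    reports <- list(descriptor = reports)
  }
  out <- lapply(reports, function(rep) {
    rng <- rep$params$gradient_range
    cuts <- sort(rep$ridges$position)
    edges <- c(rng[1], cuts, rng[2])
    list(thresholds = cuts,
         valleys = sort(rep$valleys$position),
         regimes = data.frame(from = edges[-length(edges)],
                              to = edges[-1]),
         baseline = rep$baseline)
  })
  structure(out, class = c("guardrail_summary", "list"))
}

#' @export
print.guardrail_summary <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ": guardrails at",
        if (length(x[[nm]]$thresholds)) {
          paste(signif(x[[nm]]$thresholds, 3), collapse = ", ")
        } else "none",
        sprintf("(%d regimes)\n", nrow(x[[nm]]$regimes)))
  }
  invisible(x)
}
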