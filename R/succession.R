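#' Similarity of each station's community to a reference station
#'
#' Builds the distance-decay series for one water mass: for every station
#' carrying that water mass, the Bray-Curtis similarity between its
#' community and the reference station's community, paired with the
#' along-path distance between them.  When the water mass comprises
#' several depth sub-layers per station (e.g. the upper/middle/lower NADW),
#' similarities are computed between matching sub-layers and either
#' averaged per station (default, one pooled series) or returned as
#' separate per-sub-layer points.
#'
#' @param resemblance A `resemblance` similarity matrix over all samples.
#' @param layout data.frame with columns `sample_id`, `station`, `layer`,
#'   `water_mass`, `along_path_km` and optionally `region` (e.g. a
#'   scenario's `metadata`).
#' @param water_mass Water-mass label selecting the series.
#' @param reference_station Station id of the reference (its own point has
#'   similarity 100 at distance 0).
#' @param sublayers "mean" (default) or "separate".
#' @return Object of class `succession_series`: data.frame with columns
#'   `station`, `region`, `distance_km`, `similarity` (and `layer` when
#'   `sublayers = "separate"`), with attributes `water_mass` and
#'   `reference_station`.
#' @export
similarity_to_reference <- function(resemblance, layout, water_mass,
                                    reference_station,
                                    sublayers = c("mean", "separate")) {
  sublayers <- match.arg(sublayers)
  stopifnot(inherits(resemblance, "resemblance"))
  if (resemblance$kind != "similarity-percent")
    stop("a similarity-percent resemblance matrix is required",
         call. = FALSE)
  need <- c("sample_id", "station", "layer", "water_mass", "along_path_km")
  miss <- setdiff(need, names(layout))
  if (length(miss) > 0)
    stop("layout lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"region" %in% names(layout)) layout$region <- "transect"
  sel <- layout[layout$water_mass == water_mass, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no samples in water mass '", water_mass, "'", call. = FALSE)
  ref <- sel[sel$station == reference_station, , drop = FALSE]
  if (nrow(ref) == 0)
    stop("reference station '", reference_station,
         "' absent from water mass '", water_mass, "'", call. = FALSE)
  S <- resemblance$values
  absent <- setdiff(sel$sample_id, rownames(S))
  if (length(absent) > 0)
    stop("samples missing from resemblance matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  ref_km <- ref$along_path_km[1]
  rows <- list()
  for (st in unique(sel$station)) {
    sub <- sel[sel$station == st, , drop = FALSE]
    common <- intersect(sub$layer, ref$layer)
    if (length(common) == 0) next
    sims <- vapply(common, function(ly)
      S[sub$sample_id[sub$layer == ly], ref$sample_id[ref$layer == ly]], 0)
    d <- abs(sub$along_path_km[1] - ref_km)
    if (sublayers == "mean") {
      rows[[length(rows) + 1]] <- data.frame(
        station = st, region = sub$region[1], distance_km = d,
        similarity = mean(sims), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        station = st, region = sub$region[1], layer = common,
        distance_km = d, similarity = sims, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # canonical ordering: the chain stays invariant to input sample order
  out <- out[order(out$distance_km, out$station), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, water_mass = water_mass,
            reference_station = reference_station,
            class = c("succession_series", "data.frame"))
}

series_points <- function(series, include_reference = FALSE) {
  pts <- data.frame(x = series$distance_km, y = series$similarity)
  if (!include_reference) pts <- pts[pts$x > 0, , drop = FALSE]
  pts
}

#' Ordinary least-squares distance-decay regression
#'
#' Regresses similarity (percent) on along-path distance (km).  The
#' reference station's self-comparison point (100\% at 0 km) is excluded
#' by default: it is not an observation of between-station similarity.
#'
#' @param series A `succession_series` (or data.frame with `distance_km`
#'   and `similarity`).
#' @param include_reference Keep the zero-distance self point
#'   (default FALSE).
#' @return Object of class `decay_fit`: list with `slope` (percent per
#'   km), `intercept`, `r_squared`, `n`, `p_parametric`.
#' @export
fit_distance_decay <- function(series, include_reference = FALSE) {
  pts <- series_points(series, include_reference)
  if (nrow(pts) < 3)
    stop("need at least 3 points for a regression", call. = FALSE)
  if (stats::sd(pts$x) == 0)
    stop("zero variance in distances", call. = FALSE)
  fit <- stats::lm(y ~ x, data = pts)
  # exact lines are legitimate here (noise-free synthetic scenarios);
  # silence summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  p_par <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4]
           else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = nrow(pts),
                 p_parametric = p_par),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("slope = %.4g %%/km, R2 = %.3f, n = %d, p = %.3g\n",
              x$slope, x$r_squared, x$n, x$p_parametric))
  invisible(x)
}

# closed-form OLS slopes for a matrix of resampled index rows (one
# replicate per row); returns NA where x has no variance
boot_slopes <- function(x, y, idx) {
  n <- ncol(idx)
  X <- matrix(x[idx], nrow(idx), n)
  Y <- matrix(y[idx], nrow(idx), n)
  sx <- rowSums(X); sy <- rowSums(Y)
  den <- n * rowSums(X * X) - sx^2
  num <- n * rowSums(X * Y) - sx * sy
  ifelse(den > 0, num / den, NA_real_)
}

#' Bootstrap test of the distance-decay slope
#'
#' Because every point of the series shares the single reference sample,
#' the points are not independent; stations are therefore resampled with
#' replacement as whole units and the OLS slope refit per replicate.
#' Replicates with fewer than 3 distinct distances are redrawn.  Reports
#' the percentile 95\% confidence interval and a two-sided bootstrap
#' p-value for H0: slope = 0,
#' p = 2 * min((1 + #\{slope <= 0\}), (1 + #\{slope >= 0\})) / (1 + n_boot).
#'
#' @param series A `succession_series`.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Optional integer seed.
#' @param include_reference Keep the zero-distance self point
#'   (default FALSE).
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @return Object of class `slope_test`: list with `observed_slope`,
#'   `boot_mean`, `ci_low`, `ci_high`, `n_boot`, `p_bootstrap`, and the
#'   replicate `slopes`.
#' @export
bootstrap_slope <- function(series, n_boot = 10000, seed = NULL,
                            include_reference = FALSE, conf = 0.95) {
  pts <- series_points(series, include_reference)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points to bootstrap", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- unname(stats::coef(stats::lm(y ~ x, data = pts))[2])
  distinct <- function(M) apply(matrix(pts$x[M], nrow(M), n), 1,
                                function(r) length(unique(r)))
  draw <- function(k) {
    idx <- matrix(sample.int(n, k * n, replace = TRUE), k, n)
    s <- boot_slopes(pts$x, pts$y, idx)
    s[distinct(idx) < 3] <- NA_real_  # replicate uninformative: redraw
    s
  }
  slopes <- draw(n_boot)
  tries <- 0L
  while (anyNA(slopes) && tries < 100L) {
    bad <- which(is.na(slopes))
    slopes[bad] <- draw(length(bad))
    tries <- tries + 1L
  }
  slopes <- slopes[!is.na(slopes)]
  ci <- unname(stats::quantile(slopes, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  p <- 2 * min((1 + sum(slopes <= 0)) / (1 + length(slopes)),
               (1 + sum(slopes >= 0)) / (1 + length(slopes)))
  p <- min(p, 1)
  if (n_boot < 100)
    warning("n_boot < 100: bootstrap interval has low precision")
  structure(list(observed_slope = obs, boot_mean = mean(slopes),
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = length(slopes), p_bootstrap = p, slopes = slopes),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "slope = %.4g %%/km, 95%% CI [%.4g, %.4g], p_boot = %.3g (%d reps)\n",
    x$observed_slope, x$ci_low, x$ci_high, x$p_bootstrap, x$n_boot))
  invisible(x)
}

#' ANCOVA comparison of the observed slope against a permutation null
#'
#' Generates a null ensemble by shuffling the similarity values across the
#' distance labels of the series (destroying any distance-decay while
#' keeping the marginal distributions), pools the observed points with all
#' null replicates under a group indicator, and tests homogeneity of
#' slopes via the F-test on the distance-by-group interaction.
#'
#' @param series A `succession_series`.
#' @param n_null Number of permutation replicates (default 1000).
#' @param seed Optional integer seed.
#' @param include_reference Keep the zero-distance self point
#'   (default FALSE).
#' @return List with `ancova_F`, `ancova_p`, `n_null`.
#' @export
ancova_slope_test <- function(series, n_null = 1000, seed = NULL,
                              include_reference = FALSE) {
  pts <- series_points(series, include_reference)
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  if (n_null < 1) stop("empty null ensemble", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null_y <- replicate(n_null, sample(pts$y))
  pooled <- data.frame(
    x = c(pts$x, rep(pts$x, n_null)),
    y = c(pts$y, as.vector(null_y)),
    g = factor(rep(c("observed", "null"), c(nrow(pts), nrow(pts) * n_null)),
               levels = c("null", "observed"))
  )
  fit <- stats::lm(y ~ x * g, data = pooled)
  av <- stats::anova(fit)
  row <- which(rownames(av) == "x:g")
  list(ancova_F = av[row, "F value"], ancova_p = av[row, "Pr(>F)"],
       n_null = as.integer(n_null))
}

#' Full succession analysis across water masses and regions
#'
#' For every requested water mass (and within it, each station region:
#' fracture-zone transect vs. off-path continuation), builds the
#' similarity-to-reference series, fits the distance-decay regression, and
#' runs both slope tests: the station bootstrap for H0: slope = 0 and the
#' ANCOVA comparison against a permutation null.
#'
#' @param fingerprints Sample x OTU/bin matrix (e.g. a
#'   `fingerprint_matrix`), or a precomputed `resemblance` similarity
#'   matrix.
#' @param layout Sample layout (see [similarity_to_reference()]).
#' @param water_masses Water masses to analyse (default: all in `layout`).
#' @param reference_station Reference station id (default: the station
#'   with the smallest along-path distance).
#' @param n_boot,n_null Replication counts for the two tests.
#' @param seed Optional integer seed (streams for the two tests are
#'   derived from it).
#' @param regions Analyse station regions separately (default TRUE).
#' @param min_points Minimum points for a regression row (default 4).
#' @return data.frame with one row per water mass x region: `water_mass`,
#'   `region`, `n`, `slope`, `r2`, `ci_low`, `ci_high`, `p_bootstrap`,
#'   `ancova_F`, `ancova_p`.
#' @export
run_succession_analysis <- function(fingerprints, layout,
                                    water_masses = NULL,
                                    reference_station = NULL,
                                    n_boot = 10000, n_null = 1000,
                                    seed = NULL, regions = TRUE,
                                    min_points = 4) {
  res <- if (inherits(fingerprints, "resemblance")) fingerprints
         else bray_curtis_matrix(fingerprints)
  if (is.null(water_masses)) water_masses <- unique(layout$water_mass)
  if (length(unique(layout$water_mass)) < 1)
    stop("layout carries no water masses", call. = FALSE)
  if (is.null(reference_station))
    reference_station <- layout$station[which.min(layout$along_path_km)]
  if (!"region" %in% names(layout)) layout$region <- "transect"
  out <- list()
  for (wm in water_masses) {
    series <- similarity_to_reference(res, layout, wm, reference_station)
    regs <- if (regions) unique(series$region) else "all"
    for (rg in regs) {
      sub <- if (regions) series[series$region == rg, , drop = FALSE]
             else series
      attributes(sub)[c("water_mass", "reference_station")] <-
        attributes(series)[c("water_mass", "reference_station")]
      class(sub) <- class(series)
      n_pts <- nrow(series_points(sub))
      if (n_pts < min_points) next
      fit <- fit_distance_decay(sub)
      bs <- bootstrap_slope(sub, n_boot = n_boot,
                            seed = if (is.null(seed)) NULL
                                   else derive_seed(seed, "bootstrap"))
      an <- ancova_slope_test(sub, n_null = n_null,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, "ancova"))
      out[[length(out) + 1]] <- data.frame(
        water_mass = wm, region = rg, n = n_pts,
        slope = fit$slope, r2 = fit$r_squared,
        ci_low = bs$ci_low, ci_high = bs$ci_high,
        p_bootstrap = bs$p_bootstrap,
        ancova_F = an$ancova_F, ancova_p = an$ancova_p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    stop("no water mass / region had enough points", call. = FALSE)
  do.call(rbind, out)
}
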