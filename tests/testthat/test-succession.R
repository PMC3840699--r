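make_series <- function(x, y, region = "transect") {
  structure(data.frame(station = paste0("St", seq_along(x)),
                       region = region, distance_km = x, similarity = y),
            water_mass = "NADW", reference_station = "St1",
            class = c("succession_series", "data.frame"))
}

test_that("similarity series are anchored at the reference station", {
  sc <- generate_scenario(small_config(seed = 41, noise_cv = 0),
                          sequences = FALSE)
  bc <- bray_curtis_matrix(as_sample_matrix(sc))
  ser <- similarity_to_reference(bc, sc$metadata, "NADW", "St01")
  ref <- ser[ser$station == "St01", ]
  expect_equal(ref$distance_km, 0)
  expect_equal(ref$similarity, 100)

  # zero-turnover, noise-free: everything similar at 100
  sc0 <- generate_scenario(small_config(seed = 41, succession_rate = 0,
                                        noise_cv = 0), sequences = FALSE)
  bc0 <- bray_curtis_matrix(as_sample_matrix(sc0))
  ser0 <- similarity_to_reference(bc0, sc0$metadata, "NADW", "St01")
  expect_true(all(abs(ser0$similarity - 100) < 1e-9))

  # per-sub-layer mode returns one point per station x layer
  sep <- similarity_to_reference(bc, sc$metadata, "NADW", "St01",
                                 sublayers = "separate")
  expect_equal(nrow(sep), 3 * nrow(ser))
  expect_true("layer" %in% names(sep))

  expect_error(similarity_to_reference(bc, sc$metadata, "NADW", "St99"),
               "reference station")
  expect_error(similarity_to_reference(bc, sc$metadata, "XBW", "St01"),
               "water mass")
})

test_that("distance-decay regression recovers exact lines", {
  x <- c(100, 400, 900, 1500, 2000)
  ser <- make_series(x, 90 - 0.02 * x)
  fit <- fit_distance_decay(ser)
  expect_equal(fit$slope, -0.02)
  expect_equal(fit$intercept, 90)
  expect_equal(fit$r_squared, 1)

  flat <- make_series(x, rep(55, 5))
  ffit <- fit_distance_decay(flat)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r_squared, 0)

  # the (0, 100) self point is excluded by default but can be kept
  ser2 <- make_series(c(0, x), c(100, 90 - 0.02 * x))
  expect_equal(fit_distance_decay(ser2)$n, 5)
  expect_equal(fit_distance_decay(ser2, include_reference = TRUE)$n, 6)

  expect_error(fit_distance_decay(make_series(c(10, 20), c(1, 2))),
               "3 points")
  expect_error(fit_distance_decay(make_series(rep(5, 4), 1:4)),
               "zero variance")
})

test_that("slope is equivariant under distance rescaling", {
  set.seed(42)
  x <- seq(100, 2000, length.out = 12)
  y <- 95 - 0.025 * x + rnorm(12, 0, 3)
  f_km <- fit_distance_decay(make_series(x, y))
  f_m <- fit_distance_decay(make_series(x * 1000, y))
  expect_equal(f_m$slope, f_km$slope / 1000)
  expect_equal(f_m$r_squared, f_km$r_squared)
  expect_equal(f_m$p_parametric, f_km$p_parametric)
})

test_that("noise-free scenarios yield the analytic turnover slope", {
  # mixture construction: similarity = 100 (1 - rate d), slope = -100 rate
  sc <- generate_scenario(small_config(seed = 43, noise_cv = 0,
                                       succession_rate = 2e-4),
                          sequences = FALSE)
  bc <- bray_curtis_matrix(as_sample_matrix(sc))
  ser <- similarity_to_reference(bc, sc$metadata, "NADW", "St01")
  fit <- fit_distance_decay(ser[ser$region == "transect", ])
  expect_equal(fit$slope, -100 * 2e-4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("bootstrap slope test is internally consistent", {
  set.seed(44)
  x <- seq(100, 2000, length.out = 14)

  # strong decay: CI excludes 0, small p
  y <- 95 - 0.03 * x + rnorm(14, 0, 1.5)
  bs <- bootstrap_slope(make_series(x, y), n_boot = 2000, seed = 1)
  expect_lt(bs$ci_high, 0)
  expect_lt(bs$p_bootstrap, 0.01)
  expect_equal(bs$observed_slope,
               fit_distance_decay(make_series(x, y))$slope)

  # CI and p agree on rejection across random series
  for (k in 1:10) {
    y2 <- 70 + rnorm(14, 0, 4) - 0.01 * x * (k %% 2)
    b2 <- bootstrap_slope(make_series(x, y2), n_boot = 999, seed = k)
    rej_ci <- b2$ci_low > 0 || b2$ci_high < 0
    rej_p <- b2$p_bootstrap < 0.05
    expect_equal(rej_ci, rej_p, info = paste("k =", k))
  }

  expect_warning(bootstrap_slope(make_series(x, y), n_boot = 1, seed = 1),
                 "low precision")
  expect_error(bootstrap_slope(make_series(x[1:3], y[1:3])), "4 points")
})

test_that("bootstrap p-values are never zero and CIs are ordered", {
  set.seed(45)
  x <- seq(0, 1000, length.out = 10)
  for (k in 1:5) {
    y <- 80 - 0.05 * x + rnorm(10, 0, 0.5)
    bs <- bootstrap_slope(make_series(x, y), n_boot = 500, seed = k)
    expect_gt(bs$p_bootstrap, 0)
    expect_lte(bs$ci_low, bs$ci_high)
  }
})

test_that("ANCOVA separates a real trend from its permutation null", {
  set.seed(46)
  x <- seq(100, 2000, length.out = 14)
  y <- 95 - 0.03 * x + rnorm(14, 0, 1.5)
  an <- ancova_slope_test(make_series(x, y), n_null = 500, seed = 2)
  expect_lt(an$ancova_p, 0.01)
  expect_gt(an$ancova_F, 0)

  # a flat series should usually not be separated from its null
  yf <- 60 + rnorm(14, 0, 3)
  anf <- ancova_slope_test(make_series(x, yf), n_null = 500, seed = 3)
  expect_gt(anf$ancova_p, 0.001)
  expect_error(ancova_slope_test(make_series(x, y), n_null = 0), "empty")
})

test_that("run_succession_analysis emits a tidy per-water-mass table", {
  sc <- generate_scenario(small_config(seed = 47), sequences = FALSE)
  m <- as_sample_matrix(sc)
  res <- run_succession_analysis(m, sc$metadata,
                                 water_masses = c("NADW", "AABW"),
                                 n_boot = 500, n_null = 100, seed = 9)
  expect_setequal(unique(res$water_mass), c("NADW", "AABW"))
  expect_setequal(unique(res$region), c("transect", "offpath"))
  expect_named(res, c("water_mass", "region", "n", "slope", "r2",
                      "ci_low", "ci_high", "p_bootstrap",
                      "ancova_F", "ancova_p"))
  nadw <- res[res$water_mass == "NADW" & res$region == "transect", ]
  expect_lt(nadw$p_bootstrap, 0.05)

  # single water mass: rows for that mass only
  one <- run_succession_analysis(m, sc$metadata, water_masses = "AABW",
                                 n_boot = 200, n_null = 50, seed = 9)
  expect_true(all(one$water_mass == "AABW"))
})

test_that("the analysis chain is invariant to sample ordering", {
  sc <- generate_scenario(small_config(seed = 48), sequences = FALSE)
  m <- as_sample_matrix(sc)
  set.seed(1)
  perm <- sample(nrow(m))
  r1 <- run_succession_analysis(m, sc$metadata, water_masses = "NADW",
                                n_boot = 300, n_null = 50, seed = 5)
  r2 <- run_succession_analysis(m[perm, ], sc$metadata[perm, ],
                                water_masses = "NADW",
                                n_boot = 300, n_null = 50, seed = 5)
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$r2, r2$r2)
  expect_equal(r1$p_bootstrap, r2$p_bootstrap)
})
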