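# Proportional and residual age/sex normalization: exact recovery on
# noiseless data, the printed correction formulas, and OLS orthogonality.

noiseless_hc <- function(seed = 1, slope = -0.01, intercept = 3.0,
                         n_regions = 6, n = 60) {
  cfg <- sim_config(atlas_size = n_regions, vertices_per_region = 12,
                    seed = seed,
                    baseline_mean_mm = rep(intercept, n_regions),
                    healthy_slope_mm_per_year = c(F = slope, M = slope),
                    sex_offset_mm = 0, within_patient_sd_mm = 0,
                    patient_intercept_sd_mm = 0, vertex_noise_sd_mm = 0)
  simulate_healthy_reference(cfg, n_subjects = c(amsep = n / 2, ixi = n / 2))
}

test_that("noiseless proportional fit recovers slope and intercept exactly", {
  hc <- noiseless_hc(slope = -0.01, intercept = 3.0)
  model <- fit_proportional(hc)
  for (sx in c("F", "M")) {
    expect_equal(model$coefficients[[sx]][["a"]], -0.01, tolerance = 1e-10)
    expect_equal(model$coefficients[[sx]][["b"]], 3.0, tolerance = 1e-8)
  }
})

test_that("proportional fit needs both sexes and non-constant age", {
  hc <- noiseless_hc()
  tab <- data.frame(age_years = runif(30, 20, 60), sex = "M",
                    cth = runif(30, 2, 3))
  expect_error(fit_proportional(tab), "both sexes")
  tab2 <- rbind(tab, transform(tab, sex = "F"))
  tab2$age_years <- 40
  expect_error(fit_proportional(tab2), "constant")
})

test_that("alpha equals 1 at the reference age and follows the printed formula", {
  hc <- noiseless_hc()
  model <- fit_proportional(hc)
  X <- structure(matrix(runif(24, 0, 3), 6, 4,
                        dimnames = list(1:6, c("mu", "sigma", "gamma", "k"))),
                 class = c("feature_matrix", "matrix", "array"))
  at20 <- apply_proportional(X, age = 20, sex = "F", cth = 2.4, model = model)
  expect_equal(attr(at20, "alpha"), 1, tolerance = 1e-12)
  expect_equal(unclass(at20), unclass(X), ignore_attr = TRUE)

  # a = -0.01, age = 40, Cth = 2.4: Cth20 = 2.6, alpha = 2.6/2.4
  at40 <- apply_proportional(X, age = 40, sex = "F", cth = 2.4, model = model)
  expect_equal(attr(at40, "alpha"), 2.6 / 2.4, tolerance = 1e-10)
  expect_equal(at40[, "mu"], (2.6 / 2.4) * X[, "mu"])
  expect_equal(at40[, "sigma"], (2.6 / 2.4) * X[, "sigma"])
  # third and fourth moments are untouched by the rescaling
  expect_equal(at40[, "gamma"], X[, "gamma"])
  expect_equal(at40[, "k"], X[, "k"])
})

test_that("proportional correction preserves mu ordering across regions", {
  hc <- noiseless_hc()
  model <- fit_proportional(hc)
  set.seed(2)
  X <- structure(matrix(c(sort(runif(6, 2, 3)), runif(18)), 6, 4,
                        dimnames = list(1:6, c("mu", "sigma", "gamma", "k"))),
                 class = c("feature_matrix", "matrix", "array"))
  out <- apply_proportional(X, age = 55, sex = "M", cth = 2.5, model = model)
  expect_equal(order(out[, "mu"]), order(X[, "mu"]))
  expect_error(apply_proportional(X, age = 40, sex = "F", cth = -1, model),
               "positive")
  expect_error(apply_proportional(X, age = NA, sex = "F", cth = 2, model),
               "age")
})

test_that("residual model has 2 x N x 4 coefficients and fits noiseless data exactly", {
  hc <- noiseless_hc(slope = -0.01, intercept = 2.5, n_regions = 5)
  parc <- parcellation("custom", n_regions = 5)
  feats <- featurize_cohort(hc, parc)
  model <- fit_residual(feats, hc$metadata)
  n_pairs <- sum(vapply(model$slope, length, 0L)) # slope entries across sexes
  expect_equal(n_pairs, 2 * 5 * 4)
  for (sx in c("F", "M")) {
    expect_equal(unname(model$slope[[sx]][, "mu"]), rep(-0.01, 5),
                 tolerance = 1e-10)
    expect_equal(unname(model$intercept[[sx]][, "mu"]), rep(2.5, 5),
                 tolerance = 1e-8)
    # constant-in-age statistics get slope 0
    expect_equal(unname(model$slope[[sx]][, "sigma"]), rep(0, 5),
                 tolerance = 1e-10)
  }
})

test_that("residuals follow the predicted-minus-observed orientation", {
  model <- structure(list(
    slope = list(F = matrix(0, 1, 4, dimnames = list(1, c("mu", "sigma", "gamma", "k"))),
                 M = matrix(0, 1, 4, dimnames = list(1, c("mu", "sigma", "gamma", "k")))),
    intercept = list(F = matrix(c(2.3, 0, 0, 0), 1, 4,
                                dimnames = list(1, c("mu", "sigma", "gamma", "k"))),
                     M = matrix(0, 1, 4,
                                dimnames = list(1, c("mu", "sigma", "gamma", "k")))),
    n_fit = c(F = 10, M = 10)), class = "residual_model")
  X <- structure(matrix(c(2.1, 0, 0, 0), 1, 4,
                        dimnames = list(1, c("mu", "sigma", "gamma", "k"))),
                 class = c("feature_matrix", "matrix", "array"))
  r <- apply_residual(X, age = 30, sex = "F", model = model)
  expect_equal(unname(r[1, "mu"]), 0.2)  # predicted 2.3 - observed 2.1
  rf <- apply_residual(X, age = 30, sex = "F", model = model, flip_sign = TRUE)
  expect_equal(unname(rf[1, "mu"]), -0.2)
})

test_that("residuals on the fitting set are numerically orthogonal to age", {
  cfg <- sim_config(atlas_size = 6, vertices_per_region = 20, seed = 8)
  hc <- simulate_healthy_reference(cfg, n_subjects = c(amsep = 50, ixi = 250))
  parc <- parcellation("custom", n_regions = 6)
  feats <- featurize_cohort(hc, parc)
  model <- fit_residual(feats, hc$metadata)
  res <- normalize_features(feats, hc$metadata, "residual", model)
  meta <- as.data.frame(hc$metadata)
  for (sx in c("F", "M")) {
    ids <- meta$scan_id[meta$sex == sx]
    age <- meta$age_years[match(ids, meta$scan_id)]
    rmu <- t(vapply(res[ids], function(X) X[, "mu"], numeric(6)))
    for (r in 1:6) expect_lt(abs(cor(rmu[, r], age)), 1e-10)
  }
  # scans generated exactly on the regression surface give zero residuals
  hc0 <- noiseless_hc(slope = -0.005, intercept = 2.8, n_regions = 6)
  feats0 <- featurize_cohort(hc0, parcellation("custom", n_regions = 6))
  model0 <- fit_residual(feats0, hc0$metadata)
  res0 <- apply_residual(feats0[[1]],
                         age = hc0$metadata$age_years[1],
                         sex = hc0$metadata$sex[1], model0)
  expect_equal(unname(res0[, "mu"]), rep(0, 6), tolerance = 1e-8)
})

test_that("region mismatch between matrix and model is an error", {
  hc <- noiseless_hc(n_regions = 5)
  feats <- featurize_cohort(hc, parcellation("custom", n_regions = 5))
  model <- fit_residual(feats, hc$metadata)
  Xbig <- structure(matrix(0, 7, 4,
                           dimnames = list(1:7, c("mu", "sigma", "gamma", "k"))),
                    class = c("feature_matrix", "matrix", "array"))
  expect_error(apply_residual(Xbig, 30, "F", model), "mismatch")
})

test_that("normalization models serialize to JSON and back", {
  hc <- noiseless_hc(n_regions = 4)
  pm <- fit_proportional(hc)
  feats <- featurize_cohort(hc, parcellation("custom", n_regions = 4))
  rm <- fit_residual(feats, hc$metadata)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_norm_model(pm, p1)
  write_norm_model(rm, p2)
  pm2 <- read_norm_model(p1)
  rm2 <- read_norm_model(p2)
  expect_equal(pm2$coefficients$F[["a"]], pm$coefficients$F[["a"]])
  expect_equal(unname(rm2$slope$M), unname(rm$slope$M))
  expect_equal(unname(rm2$intercept$F), unname(rm$intercept$F))
})
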