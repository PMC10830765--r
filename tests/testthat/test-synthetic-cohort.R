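# Cohort simulator: determinism, study-scale counts, physical bounds,
# null-effect behaviour and age-slope recovery.

test_that("default configuration reproduces the study-scale scan counts", {
  cfg <- sim_config(atlas_size = 4, vertices_per_region = 2, seed = 1)
  coh <- simulate_cohort(cfg)
  counts <- table(coh$metadata$label)
  expect_equal(unname(counts[["RR"]]), 299)
  expect_equal(unname(counts[["PP"]]), 143)
  expect_equal(unname(counts[["SP"]]), 218)
  expect_equal(unname(counts[["HC"]]), 21)
  pats <- unique(coh$metadata[, c("patient_id", "label")])
  expect_equal(unname(table(pats$label)[c("RR", "PP", "SP", "HC")]),
               c(42L, 21L, 28L, 21L), ignore_attr = TRUE)
})

test_that("healthy reference has 335 single-scan subjects over a wide age range", {
  cfg <- sim_config(atlas_size = 4, vertices_per_region = 2, seed = 2)
  hc <- simulate_healthy_reference(cfg)
  expect_equal(nrow(hc$metadata), 335)
  expect_equal(length(unique(hc$metadata$patient_id)), 335)
  expect_equal(sum(hc$metadata$cohort == "AMSEP"), 21)
  expect_equal(sum(hc$metadata$cohort == "IXI"), 314)
  expect_true(all(hc$metadata$age_years >= 20 & hc$metadata$age_years <= 86.2))
})

test_that("identical seed and config give byte-identical tables", {
  cfg <- sim_config(atlas_size = 6, vertices_per_region = 10, seed = 7,
                    n_patients_per_class = c(RR = 3, HC = 2),
                    scans_per_class = c(RR = 8, HC = 2))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$thickness, b$thickness)
  # and a different seed changes the draws
  cfg2 <- sim_config(atlas_size = 6, vertices_per_region = 10, seed = 8,
                     n_patients_per_class = c(RR = 3, HC = 2),
                     scans_per_class = c(RR = 8, HC = 2))
  expect_false(identical(simulate_cohort(cfg2)$thickness, a$thickness))
})

test_that("thickness stays at or above the 0.5 mm floor and ages in range", {
  cfg <- sim_config(atlas_size = 10, vertices_per_region = 50, seed = 4,
                    n_patients_per_class = c(RR = 4, HC = 3),
                    scans_per_class = c(RR = 12, HC = 3),
                    vertex_noise_sd_mm = 1.5)  # heavy noise to hit the floor
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$thickness$thickness_mm >= 0.5))
  expect_true(all(coh$metadata$age_years >= 20 & coh$metadata$age_years <= 86))
  expect_true(all(coh$thickness$region_id >= 1 & coh$thickness$region_id <= 10))
})

test_that("zero class effect leaves region means indistinguishable between classes", {
  # one scan per patient so scans are independent draws; demographics are
  # equalized so the only class difference could come from class_effect
  cfg <- sim_config(atlas_size = 30, vertices_per_region = 40, seed = 5,
                    n_patients_per_class = c(RR = 40, PP = 40),
                    scans_per_class = c(RR = 40, PP = 40),
                    age_at_entry = list(RR = c(38, 6), PP = c(38, 6),
                                        SP = c(38, 6), HC = NULL),
                    sex_ratio = list(RR = c(F = 20, M = 20), PP = c(F = 20, M = 20),
                                     SP = c(F = 20, M = 20), HC = c(F = 20, M = 20)),
                    # no shared random intercepts: they shift all regions of a
                    # class sample together and would make the per-region
                    # t-tests co-move instead of being independent checks
                    within_patient_sd_mm = 0, patient_intercept_sd_mm = 0,
                    class_effect = null_class_effect())
  coh <- simulate_cohort(cfg)
  parc <- parcellation("custom", n_regions = 30)
  feats <- featurize_cohort(coh, parc)
  mu <- t(vapply(feats, function(X) X[, "mu"], numeric(30)))
  lab <- coh$metadata$label[match(rownames(mu), coh$metadata$scan_id)]
  p <- vapply(seq_len(30), function(r) {
    stats::t.test(mu[lab == "RR", r], mu[lab == "PP", r])$p.value
  }, 0)
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("noiseless simulation recovers the configured age slope exactly", {
  cfg <- sim_config(atlas_size = 8, vertices_per_region = 5, seed = 6,
                    healthy_slope_mm_per_year = c(F = -0.01, M = -0.01),
                    sex_offset_mm = 0, within_patient_sd_mm = 0,
                    patient_intercept_sd_mm = 0, vertex_noise_sd_mm = 0)
  hc <- simulate_healthy_reference(cfg, n_subjects = c(amsep = 10, ixi = 40))
  cth <- tapply(hc$thickness$thickness_mm, hc$thickness$scan_id, mean)
  tab <- data.frame(cth = as.numeric(cth[hc$metadata$scan_id]),
                    age = hc$metadata$age_years)
  fit <- lm(cth ~ age, data = tab)
  expect_equal(unname(coef(fit)[2]), -0.01, tolerance = 1e-10)
})

test_that("with noise the fitted slope lies within 3 SE of the truth (n >= 300)", {
  cfg <- sim_config(atlas_size = 10, vertices_per_region = 30, seed = 9)
  hc <- simulate_healthy_reference(cfg)  # 335 scans
  cth <- tapply(hc$thickness$thickness_mm, hc$thickness$scan_id, mean)
  tab <- data.frame(cth = as.numeric(cth[hc$metadata$scan_id]),
                    age = hc$metadata$age_years,
                    sex = hc$metadata$sex)
  for (sx in c("F", "M")) {
    fit <- summary(lm(cth ~ age, data = tab[tab$sex == sx, ]))
    truth <- if (sx == "F") -0.004 else -0.005
    expect_lt(abs(fit$coefficients["age", "Estimate"] - truth),
              3 * fit$coefficients["age", "Std. Error"])
  }
})

test_that("between-class separation grows monotonically with the effect size", {
  sep <- vapply(c(0, 0.5, 1), function(d) {
    cfg0 <- sim_config(atlas_size = 12, vertices_per_region = 30, seed = 10)
    eff <- standardized_effect_mm(cfg0, d)
    cfg <- sim_config(atlas_size = 12, vertices_per_region = 30, seed = 10,
                      n_patients_per_class = c(RR = 15, PP = 15),
                      scans_per_class = c(RR = 15, PP = 15),
                      class_effect = list(
                        RR = list(regions = integer(0), effect_mm = 0),
                        PP = list(regions = 1:3, effect_mm = eff)))
    coh <- simulate_cohort(cfg)
    feats <- featurize_cohort(coh, parcellation("custom", n_regions = 12))
    mu <- t(vapply(feats, function(X) X[1:3, "mu"], numeric(3)))
    lab <- coh$metadata$label[match(rownames(mu), coh$metadata$scan_id)]
    dvals <- vapply(1:3, function(r) {
      x <- mu[lab == "RR", r]; y <- mu[lab == "PP", r]
      (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
    }, 0)
    mean(dvals)
  }, 0)
  expect_true(all(diff(sep) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_patients_per_class = c(RR = 0, HC = 2),
                          scans_per_class = c(RR = 0, HC = 2)),
               "positive")
  expect_error(sim_config(n_patients_per_class = c(XX = 3)), "class")
  expect_error(sim_config(class_effect = list(BAD = list(regions = 1, effect_mm = -1))),
               "unknown class")
  expect_error(sim_config(atlas_size = 10,
                          class_effect = list(RR = list(regions = 99, effect_mm = -1))),
               "out of range")
})

test_that("cohort TSV round-trip preserves the tables", {
  coh <- tiny_cohort(seed = 11, n_regions = 6, vertices = 5)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$metadata), as.data.frame(coh$metadata))
  expect_equal(back$thickness$thickness_mm, coh$thickness$thickness_mm)
})
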