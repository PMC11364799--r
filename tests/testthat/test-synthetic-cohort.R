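test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_subjects = 80, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synthetic_config(n_subjects = 80, seed = 8))
  expect_false(identical(a$pDOI, c2$pDOI))
})

test_that("noise-free measurements equal latent depth plus bias", {
  bias3 <- lapply(synthetic_config()$sequence_bias, function(b)
    c(bias = 3, sd = 0))
  cfg <- synthetic_config(n_subjects = 60, seed = 2, sequence_bias = bias3,
                          ld_latent = c(base = 0, scale = 1, sd = 0),
                          missingness = lapply(
                            synthetic_config()$missingness, function(m) {
                              m$prob <- 0; m
                            }))
  ch <- generate_cohort(cfg)
  for (nm in c("rDOI_aT2", "rDOI_aCE", "rDOI_cCE", "rTT_aT2", "LD_aCE"))
    expect_equal(ch[[nm]], ch$pDOI + 3, tolerance = 1e-12)
})

test_that("invalid configuration is rejected with the parameter name", {
  expect_error(synthetic_config(n_subjects = 0), "n_subjects")
  expect_error(synthetic_config(log_hr_per_mm = NaN), "log_hr_per_mm")
  expect_error(synthetic_config(morphology_mix = c(flat = 0.5,
                                                   ulcerative = 0.2,
                                                   exophytic = 0.2)),
               "morphology_mix")
  sb <- synthetic_config()$sequence_bias
  sb$rDOI_aCE <- c(bias = 3, sd = -1)
  expect_error(synthetic_config(sequence_bias = sb), "rDOI_aCE")
  expect_error(synthetic_config(step_hazard = list(cutoffs = c(12, 8),
                                                   log_hrs = c(0, 1, 2))),
               "cutoffs")
})

test_that("basic outcome invariants hold", {
  ch <- generate_cohort(synthetic_config(n_subjects = 400, seed = 3))
  expect_true(all(ch$time > 0))
  expect_true(all(ch$event %in% c(0, 1)))
  meas <- setdiff(cohort_roles(ch)$measurements,
                  c("rTTmax", "rDOImax", "LDmax"))
  for (nm in meas) expect_true(all(ch[[nm]][!is.na(ch[[nm]])] >= 0.1))
})

test_that("max columns are row-wise maxima over non-missing members", {
  ch <- generate_cohort(synthetic_config(n_subjects = 300, seed = 4))
  rdoi <- as.matrix(as.data.frame(ch)[, c("rDOI_aT2", "rDOI_aCE",
                                          "rDOI_cCE")])
  expected <- apply(rdoi, 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  expect_equal(ch$rDOImax, unname(expected))
})

test_that("missingness rates match the configured probability", {
  ms <- lapply(synthetic_config()$missingness, function(m) {
    m$prob <- 0; m
  })
  ms$rDOI_aCE$prob <- 0.1
  ch <- generate_cohort(synthetic_config(n_subjects = 4000, seed = 5,
                                         missingness = ms))
  p_hat <- mean(is.na(ch$rDOI_aCE))
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  expect_false(anyNA(ch$rDOI_aT2))
})

test_that("MAR missingness depends on the conditioning covariate", {
  ms <- lapply(synthetic_config()$missingness, function(m) {
    m$prob <- 0; m
  })
  ms$rDOI_aCE <- list(prob = 0.2, mechanism = "MAR", covariate = "age",
                      delta = 1.5)
  ch <- generate_cohort(synthetic_config(n_subjects = 4000, seed = 6,
                                         missingness = ms))
  old <- ch$age > median(ch$age)
  expect_gt(mean(is.na(ch$rDOI_aCE[old])),
            mean(is.na(ch$rDOI_aCE[!old])))
})

test_that("event fraction is monotone in the baseline-hazard scale and the
           extremes are representable", {
  fracs <- vapply(c(50, 230, 2000), function(sc) {
    cfg <- synthetic_config(n_subjects = 500, seed = 9,
                            baseline_hazard = c(shape = 1.1, scale = sc))
    mean(generate_cohort(cfg)$event)
  }, 0)
  expect_true(all(diff(fracs) < 0))
  all_ev <- generate_cohort(synthetic_config(
    n_subjects = 200, seed = 9,
    baseline_hazard = c(shape = 1.1, scale = 0.5)))
  expect_equal(mean(all_ev$event), 1)
  none <- generate_cohort(synthetic_config(
    n_subjects = 200, seed = 9,
    baseline_hazard = c(shape = 1.1, scale = 1e7)))
  expect_equal(mean(none$event), 0)
})

test_that("Bland-Altman recovers the configured sequence bias and noise", {
  cfg <- synthetic_config(n_subjects = 5000, seed = 10,
                          morphology_mix = c(flat = 1, ulcerative = 0,
                                             exophytic = 0))
  ch <- generate_cohort(cfg)
  ba <- bland_altman(ch$rDOI_aCE, ch$pDOI)
  expect_lt(abs(ba$bias - 3.3), 3 * 4.0 / sqrt(ba$n))
  expect_lt(abs(ba$sd - 4.0), 3 * 4.0 / sqrt(2 * ba$n))
})

test_that("observer replicates cover the requested fraction and respect the
           noise setting", {
  cfg <- complete_config(n = 280, seed = 11)
  ch <- generate_cohort(cfg)
  ch2 <- generate_observer_replicates(ch, cfg, fraction = 0.1)
  expect_equal(sum(!is.na(ch2$repeat_rDOI_aCE)), 28)
  expect_length(attr(ch2, "replicate_subjects"), 28)
  expect_error(generate_observer_replicates(ch, cfg, fraction = 0),
               "fraction")

  cfg0 <- synthetic_config(n_subjects = 50, seed = 12,
                           observer_noise_sd = 0)
  ch0 <- generate_cohort(cfg0)
  ch0 <- generate_observer_replicates(ch0, cfg0, fraction = 1)
  expect_equal(ch0$repeat_rDOI_aCE, ch0$rDOI_aCE)
  expect_equal(ch0$observer2_rTT_aT2, ch0$rTT_aT2)
})

test_that("configuration round-trips through YAML", {
  cfg <- step_config(n = 40, seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  # YAML stores decimals: equality up to serialization precision
  expect_equal(as.data.frame(generate_cohort(cfg2)),
               as.data.frame(generate_cohort(cfg)), tolerance = 1e-9)
})

test_that("univariate Cox on latent depth recovers the per-mm hazard ratio", {
  cfg <- synthetic_config(n_subjects = 5000, seed = 14,
                          censor_dist = c(min = 60, max = 180))
  ch <- generate_cohort(cfg)
  fit <- cox_fit(data.frame(pDOI = ch$pDOI), ch$time, ch$event)
  expect_gt(fit$coefficients$hr, 1.06)
  expect_lt(fit$coefficients$hr, 1.10)
})
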