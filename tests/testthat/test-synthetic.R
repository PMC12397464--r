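test_that("make_covariance scales target rows and stays positive definite", {
  # identity case: no modulation leaves all rows equal to base
  s0 <- make_covariance(5, 0.3, target_roi = 2, modulation = 0)
  expect_equal(s0[upper.tri(s0)], rep(0.3, 10))
  expect_equal(diag(s0), rep(1, 5))

  # direct arithmetic on a 3-ROI matrix
  s <- make_covariance(3, 0.3, target_roi = 1, modulation = 0.5)
  expect_equal(s[1, 2], 0.45)
  expect_equal(s[1, 3], 0.45)
  expect_equal(s[2, 3], 0.3)
  expect_equal(diag(s), rep(1, 3))
  expect_true(isSymmetric(s))

  # always positive definite across a modulation grid, multi-target included
  for (m in seq(-0.5, 0.5, by = 0.25)) {
    sm <- make_covariance(20, 0.3, target_roi = c(3, 4), modulation = m)
    expect_gt(min(eigen(sm, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  }
})

test_that("population degree of the target increases with modulation", {
  # evaluate the weighted degree on the exact population z-matrix (no
  # sampling): the plant must be monotone in the modulation
  grid <- seq(-0.5, 0.5, by = 0.1)
  deg <- vapply(grid, function(m) {
    s <- make_covariance(30, 0.3, target_roi = 1, modulation = m)
    z <- atanh(pmin(pmax(cov2cor(s), -0.999999), 0.999999))
    diag(z) <- 0
    sum(z[1, ])
  }, numeric(1))
  expect_true(all(diff(deg) > 0))
})

test_that("simulate_timeseries reproduces the innovation correlation structure", {
  # identity covariance, no autocorrelation: off-diagonals near zero
  ts <- simulate_timeseries(diag(4), n_volumes = 100000, ar_coefficient = 0,
                            seed = 11)
  r <- cor(ts$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)

  # planted r = 0.6 between ROIs 1 and 2 recovered within Fisher-z tolerance
  s <- diag(3); s[1, 2] <- s[2, 1] <- 0.6
  ts2 <- simulate_timeseries(s, n_volumes = 50000, ar_coefficient = 0.3,
                             seed = 12)
  expect_gt(cor(ts2$data)[1, 2], 0.58)
  expect_lt(cor(ts2$data)[1, 2], 0.62)
})

test_that("simulate_timeseries is deterministic in the seed and warns on short series", {
  s <- make_covariance(6, 0.3, 1, 0.2)
  a <- suppressWarnings(simulate_timeseries(s, 50, 0.4, seed = 5))
  b <- suppressWarnings(simulate_timeseries(s, 50, 0.4, seed = 5))
  expect_identical(a$data, b$data)
  expect_warning(simulate_timeseries(s, 50, 0.4, seed = 5), "noisy")
  expect_silent(simulate_timeseries(diag(3), 60, 0, seed = 5))
})

test_that("simulated lag-1 autocorrelation matches the AR coefficient", {
  ts <- simulate_timeseries(diag(2), n_volumes = 20000, ar_coefficient = 0.5,
                            seed = 3)
  x <- ts$data[, 1]
  expect_equal(cor(x[-1], x[-length(x)]), 0.5, tolerance = 0.05)
})

test_that("phenotype generation matches the planted chain and marginals", {
  truth <- ground_truth(path_a = -0.5, path_b = 0.5, path_c_prime = 0, seed = 9)
  out <- generate_phenotypes(truth, n_subjects = 5000, seed = 9)
  ph <- out$phenotypes

  expect_equal(mean(ph$resilience), 28.4, tolerance = 0.5)
  expect_equal(sd(ph$resilience), 5.63, tolerance = 0.5)
  expect_true(all(ph$resilience >= 0 & ph$resilience <= 45))
  expect_true(all(ph$age >= 60 & ph$age <= 79))
  expect_true(all(ph$education >= 0))
  expect_true(all(ph$speed >= 0))
  expect_equal(mean(ph$sex), 73 / 101, tolerance = 0.03)

  # a-path slope recovered by OLS on the generated data
  fit <- lm(out$latent ~ scale(ph$resilience))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("null phenotypes show no resilience-speed association", {
  truth <- ground_truth(path_a = 0, path_b = 0, path_c_prime = 0,
                        covariate_effects = c(age = 0, sex = 0, education = 0))
  out <- generate_phenotypes(truth, n_subjects = 5000, seed = 21)
  r <- cor(out$phenotypes$resilience, out$phenotypes$speed)
  # |r| bound for n = 5000 independent draws (about 3.5 / sqrt(n))
  expect_lt(abs(r), 0.05)
})

test_that("zero-noise chain makes speed an exact function of resilience", {
  truth <- ground_truth(path_a = -0.6, path_b = -0.6, path_c_prime = 0,
                        covariate_effects = c(age = 0, sex = 0, education = 0),
                        noise_sds = c(latent = 0, speed = 0))
  out <- generate_phenotypes(truth, n_subjects = 200, seed = 4)
  # before integer rounding the chain is affine: on the generated scale the
  # relationship is monotone increasing (a*b > 0) and essentially perfect
  expect_gt(cor(out$phenotypes$resilience, out$phenotypes$speed,
                method = "spearman"), 0.99)
})

test_that("motion generator honours the spike rate and determinism", {
  # no spikes, no steps -> all-zero motion and zero FD downstream
  m0 <- generate_motion(50, spike_probability = 0, seed = 1,
                        step_sd_translation = 0, step_sd_rotation = 0)
  expect_true(all(m0$motion6 == 0))
  expect_true(all(framewise_displacement(m0$motion6) == 0))

  # expected flagged-volume count before neighbour expansion ~ (n-1) p
  counts <- vapply(1:200, function(s) {
    cf <- generate_motion(235, spike_probability = 0.05, seed = s)
    sum(framewise_displacement(cf$motion6) > 0.5)
  }, numeric(1))
  expect_equal(mean(counts), 234 * 0.05, tolerance = 0.1 * 234 * 0.05)

  a <- generate_motion(100, 0.05, seed = 7)
  b <- generate_motion(100, 0.05, seed = 7)
  expect_identical(a$motion6, b$motion6)
  expect_identical(a$tissue_signals, b$tissue_signals)
})

test_that("cohorts share ids and ordering across components", {
  coh <- tiny_cohort(seed = 2)
  ids <- vapply(coh$timeseries, function(t) t$subject_id, character(1))
  expect_identical(ids, coh$phenotypes$subject_id)
  expect_length(coh$confounds, length(coh$timeseries))
  expect_identical(validate_inputs(coh)$issue, character(0))
  # regenerating with the same seed is bit-identical (pure function of seed)
  coh2 <- tiny_cohort(seed = 2)
  expect_identical(coh$timeseries[[3]]$data, coh2$timeseries[[3]]$data)
  expect_identical(coh$phenotypes, coh2$phenotypes)
})

test_that("cohort files round-trip through a directory", {
  coh <- tiny_cohort(seed = 3, n_subjects = 10)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$phenotypes$resilience, coh$phenotypes$resilience)
  expect_equal(back$timeseries[[2]]$data, coh$timeseries[[2]]$data,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$truth$path_a, coh$truth$path_a)
  expect_identical(validate_inputs(back)$issue, character(0))
})
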