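make_ts <- function(data, tr = 2) subject_timeseries(data, "s1", tr_seconds = tr)

test_that("discard_initial removes exactly the leading volumes", {
  ts <- make_ts(matrix(seq_len(240 * 3), 240, 3))
  expect_equal(nrow(discard_initial(ts)$data), 235)
  expect_identical(discard_initial(ts, 0), ts)
  small <- make_ts(matrix(1:30, 10, 3))
  expect_equal(discard_initial(small, 5)$data, small$data[6:10, ],
               ignore_attr = TRUE)
  expect_error(discard_initial(small, 10), "cannot discard")
})

test_that("framewise displacement follows the L1 + arc-length definition", {
  const <- matrix(5, 20, 6)
  expect_equal(framewise_displacement(const), rep(0, 20))

  m <- matrix(0, 20, 6)
  m[10:20, 1] <- 1 # +1 mm step at volume 10
  fd <- framewise_displacement(m)
  expect_equal(fd[10], 1)
  expect_equal(sum(fd), 1)

  r <- matrix(0, 20, 6)
  r[5:20, 4] <- 0.01 # 0.01 rad step -> 50 * 0.01 = 0.5 mm arc
  expect_equal(framewise_displacement(r)[5], 0.5)
  expect_equal(framewise_displacement(r, rotation_radius_mm = 100)[5], 1)
  expect_equal(framewise_displacement(m)[1], 0)
})

test_that("scrub regressors flag {t-1, t, t+1, t+2} with de-duplication", {
  expect_equal(ncol(build_scrub_regressors(rep(0.1, 20))), 0)

  fd <- rep(0, 20); fd[10] <- 0.7
  sp <- build_scrub_regressors(fd)
  expect_equal(ncol(sp), 4)
  expect_equal(as.integer(colnames(sp)), c(9, 10, 11, 12))
  expect_true(all(colSums(sp) == 1))

  # overlapping exceedances at t = 3 and t = 5: union {2..7}, 6 columns
  fd2 <- rep(0, 20); fd2[c(3, 5)] <- 1
  sp2 <- build_scrub_regressors(fd2)
  expect_equal(as.integer(colnames(sp2)), 2:7)

  # boundary clamping: exceedance at the first volume
  fd3 <- rep(0, 5); fd3[1] <- 1
  expect_equal(as.integer(colnames(build_scrub_regressors(fd3))), 1:3)
})

test_that("Friston-24 expansion has the fixed block structure", {
  z <- matrix(0, 10, 6)
  expect_true(all(expand_friston24(z) == 0))

  const <- matrix(3, 10, 6)
  f <- expand_friston24(const)
  expect_true(all(f[, 7:12] == 0))          # derivatives of a constant
  expect_true(all(f[, 13:18] == 9))         # squares
  expect_true(all(f[-1, 19:24] == 0))

  ramp <- matrix(0, 10, 6); ramp[, 2] <- 1:10
  f2 <- expand_friston24(ramp)
  expect_equal(f2[, 8], c(0, rep(1, 9)))    # finite difference of a ramp
  expect_equal(f2[, 14], (1:10)^2)
})

test_that("confound regression produces orthogonal residuals", {
  set.seed(42)
  y <- matrix(rnorm(500), 100, 5)
  x <- matrix(rnorm(300), 100, 3)
  res <- regress_confounds(make_ts(y), x)$data

  # matches an independent normal-equations solve
  dm <- cbind(1, x)
  oracle <- y - dm %*% solve(crossprod(dm), crossprod(dm, y))
  expect_equal(res, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # residuals orthogonal to every confound column
  for (j in 1:3) {
    expect_lt(max(abs(crossprod(x[, j], res))) /
                (sqrt(sum(x[, j]^2)) * max(sqrt(colSums(res^2)))), 1e-8)
  }

  # no confounders -> demeaning; confounder equal to a column -> ~0 residual
  expect_equal(regress_confounds(make_ts(y))$data, scale(y, scale = FALSE),
               ignore_attr = TRUE)
  res2 <- regress_confounds(make_ts(y), y[, 1])$data
  expect_lt(max(abs(res2[, 1])), 1e-10)
  expect_error(regress_confounds(make_ts(y[1:4, ]), matrix(rnorm(20), 4, 5)),
               "regressors")
})

test_that("band-pass keeps in-band and removes out-of-band sinusoids", {
  t_sec <- (0:199) * 2 # TR = 2 s
  amp_after <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t_sec)
    filt <- bandpass(make_ts(cbind(x, x)))$data[, 1]
    # amplitude via the dominant FFT coefficient
    max(Mod(fft(filt))) / max(Mod(fft(x)))
  }
  expect_gt(amp_after(0.05), 0.9)  # in band
  expect_lt(amp_after(0.2), 0.1)   # out of band
  expect_lt(amp_after(0.005), 0.1) # below the band

  const <- bandpass(make_ts(matrix(7, 100, 2)))$data
  expect_lt(max(abs(const)), 1e-10)

  expect_error(bandpass(make_ts(matrix(rnorm(100), 50, 2)), high_hz = 0.3),
               "Nyquist")
})

test_that("cleaning then correlating white noise is unbiased", {
  offdiag <- vapply(1:100, function(s) {
    set.seed(s)
    ts <- make_ts(matrix(rnorm(120 * 4), 120, 4))
    conf <- matrix(rnorm(120 * 3), 120, 3)
    cleaned <- bandpass(regress_confounds(ts, conf))
    r <- correlation_matrix(cleaned)
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(offdiag)), 0.02)
})

test_that("QC filter applies the screening and motion rules", {
  base <- tibble::tibble(
    subject_id = "s", max_abs_translation_mm = 1, max_abs_rotation_deg = 1,
    mean_fd = 0.1, moca = 25L, gds = 3L
  )
  vary <- function(...) {
    d <- base
    mods <- list(...)
    d[names(mods)] <- mods
    d
  }
  expect_true(qc_filter(base)$included)
  expect_equal(qc_filter(vary(moca = 21L))$reasons, "cognitive-screen")
  expect_equal(qc_filter(vary(gds = 8L))$reasons, "depression-screen")
  # mean FD over 0.2 excludes under the strict conjunction
  expect_equal(qc_filter(vary(mean_fd = 0.25))$reasons, "head-motion")
  # ... but the disjunctive reading admits it while absolute bounds hold
  expect_true(qc_filter(vary(mean_fd = 0.25), motion_rule = "disjunction")$included)
  # boundary values are all inclusive
  bound <- vary(max_abs_translation_mm = 2, max_abs_rotation_deg = 2,
                mean_fd = 0.2, moca = 22L, gds = 7L)
  expect_true(qc_filter(bound)$included)
  expect_equal(qc_filter(vary(moca = NA_integer_))$reasons, "missing-data")
  # multiple failures are all reported
  expect_equal(qc_filter(vary(moca = 20L, gds = 9L))$reasons,
               "cognitive-screen;depression-screen")
})

test_that("clean_timeseries runs the full per-subject chain deterministically", {
  coh <- tiny_cohort(seed = 5, n_subjects = 10)
  out <- clean_timeseries(coh$timeseries[[1]], coh$confounds[[1]])
  expect_equal(nrow(out$ts$data), nrow(coh$timeseries[[1]]$data) - 5)
  expect_equal(out$fd[1], 0)
  expect_true(all(out$fd >= 0))
  out2 <- clean_timeseries(coh$timeseries[[1]], coh$confounds[[1]])
  expect_identical(out$ts$data, out2$ts$data)
})
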