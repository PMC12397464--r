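# helper: generate a simple mediation dataset with known paths
med_data <- function(n, a, b, c_prime, seed, noise = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, noise)
  y <- b * m + c_prime * x + rnorm(n, 0, noise)
  tibble::tibble(x = x, m = m, y = y)
}

test_that("noiseless outcome equations are recovered exactly", {
  # the mediator keeps its own exogenous variation (otherwise x and m are
  # perfectly collinear and the model is unidentifiable, which must error)
  set.seed(1)
  x <- rnorm(50)
  m <- 2 * x + rnorm(50)     # a-path plus mediator disturbance
  y <- 3 * m + 0 * x         # zero outcome noise, c_prime = 0
  d <- tibble::tibble(x = x, m = m, y = y)
  f <- fit_paths(d, "x", "m", "y", standardize = FALSE)
  expect_equal(f$b, 3, tolerance = 1e-10)
  expect_equal(f$c_prime, 0, tolerance = 1e-10)
  expect_equal(f$indirect, 3 * f$a, tolerance = 1e-10)
  expect_equal(f$c, f$indirect, tolerance = 1e-10)
  expect_equal(f$a, 2, tolerance = 0.5)  # sample estimate of the a path

  # fully noiseless chain: m is an exact multiple of x -> unidentifiable
  d0 <- med_data(50, a = 2, b = 3, c_prime = 0, seed = 1, noise = 0)
  expect_error(fit_paths(d0, "x", "m", "y"), "rank")
})

test_that("independent mediator gives near-zero paths at large n", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(5000), m = rnorm(5000), y = rnorm(5000))
  f <- fit_paths(d, "x", "m", "y", standardize = FALSE)
  expect_lt(abs(f$a), 0.05)
  expect_lt(abs(f$b), 0.05)
  expect_lt(abs(f$indirect), 0.05)

  # an irrelevant covariate barely moves the estimates
  d$junk <- rnorm(5000)
  f2 <- fit_paths(d, "x", "m", "y", covariates = "junk", standardize = FALSE)
  expect_lt(abs(f2$a - f$a), 1e-2)
  expect_lt(abs(f2$b - f$b), 1e-2)
})

test_that("total effect decomposes as c = c_prime + a*b on every fit", {
  for (s in 1:25) {
    d <- med_data(60, a = runif(1, -1, 1), b = runif(1, -1, 1),
                  c_prime = runif(1, -1, 1), seed = s)
    d$cv <- rnorm(60)
    f <- fit_paths(d, "x", "m", "y", covariates = "cv",
                   standardize = s %% 2 == 0)
    expect_equal(f$c, f$c_prime + f$indirect, tolerance = 1e-8)
  }
})

test_that("collinear designs are rejected with a clear error", {
  d <- med_data(40, 0.5, 0.5, 0, seed = 3)
  d$dup <- d$x
  expect_error(fit_paths(d, "x", "m", "y", covariates = "dup"),
               "rank deficient|collinear")
})

test_that("bootstrap CI is seeded, bias-corrected and spec-consistent", {
  d <- med_data(150, a = 0.5, b = 0.4, c_prime = 0.2, seed = 4)
  r1 <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 9)
  r2 <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 9)
  expect_identical(r1$boot_indirects, r2$boot_indirects)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_lt(r1$ci_low, r1$indirect)
  expect_gt(r1$ci_high, r1$indirect)
  expect_identical(r1$significant, r1$ci_low > 0 || r1$ci_high < 0)

  # when the bootstrap median sits at the point estimate, BC = plain percentile
  z0 <- qnorm(mean(r1$boot_indirects < r1$indirect))
  plain <- unname(quantile(r1$boot_indirects, c(0.025, 0.975)))
  bc <- unname(quantile(r1$boot_indirects, pnorm(2 * z0 + c(-1, 1) * qnorm(0.975))))
  expect_equal(c(r1$ci_low, r1$ci_high), bc, tolerance = 1e-12)
  if (abs(z0) < 1e-12) expect_equal(c(r1$ci_low, r1$ci_high), plain)

  expect_warning(bootstrap_indirect(d, "x", "m", "y", n_boot = 500, seed = 1),
                 "unstable")
  expect_error(bootstrap_indirect(d[1:10, ], "x", "m", "y", n_boot = 1000),
               "at least 20")
})

test_that("CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(1:10, function(s) {
    d100 <- med_data(100, 0.5, 0.4, 0.2, seed = 500 + s)
    d400 <- med_data(400, 0.5, 0.4, 0.2, seed = 600 + s)
    w100 <- with(bootstrap_indirect(d100, "x", "m", "y", n_boot = 1000, seed = s),
                 ci_high - ci_low)
    w400 <- with(bootstrap_indirect(d400, "x", "m", "y", n_boot = 1000, seed = s),
                 ci_high - ci_low)
    c(w100, w400)
  }, numeric(2))
  expect_true(all(widths[2, ] < widths[1, ]))
  expect_equal(mean(widths[1, ] / widths[2, ]), 2, tolerance = 0.5)
})

test_that("mediation suite runs region and education models distinctly", {
  coh <- tiny_cohort(seed = 13, n_subjects = 40)
  tbl <- purrr::map_dfr(coh$timeseries, function(ts) {
    cm <- fisher_z(correlation_matrix(ts), ts$subject_id, ts$roi_names)
    nodal_metrics(cm, thresholds = c(0.2, 0.5))
  })
  regions <- unique(coh$atlas$region)[1:2]
  reg <- region_metrics(tbl, coh$atlas, regions = regions)
  suite <- run_mediation_suite(reg, coh$phenotypes, regions = regions,
                               n_boot = 1000, seed = 2)
  expect_equal(suite$mediator, c(regions, "education"))
  # education variant adjusts for age and sex only
  expect_equal(suite$covariates[suite$mediator == "education"], "age,sex")
  expect_true(all(suite$c - (suite$c_prime + suite$indirect) < 1e-8))

  # swapping M and Y is a different model, not a relabelling
  d <- dplyr::inner_join(reg[reg$region == regions[1], c("subject_id", "value")],
                         coh$phenotypes, by = "subject_id")
  f1 <- fit_paths(d, "resilience", "value", "speed")
  f2 <- fit_paths(d, "resilience", "speed", "value")
  expect_false(isTRUE(all.equal(f1$a, f2$a)))
  expect_false(isTRUE(all.equal(f1$indirect, f2$indirect)))
})

test_that("tidy and glance expose the fitted quantities", {
  d <- med_data(120, 0.5, 0.4, 0.1, seed = 21)
  r <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 5)
  td <- generics::tidy(r)
  expect_identical(td$term, c("a", "b", "c", "c_prime", "indirect"))
  expect_equal(td$estimate[5], r$indirect)
  expect_equal(td$conf.low[5], r$ci_low)
  gl <- generics::glance(r)
  expect_equal(gl$n, 120)
  expect_identical(gl$significant, r$significant)
})

test_that("autoplot methods return ggplot objects", {
  d <- med_data(100, 0.5, 0.4, 0.1, seed = 31)
  r <- bootstrap_indirect(d, "x", "m", "y", n_boot = 1000, seed = 5)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  pr <- permutation_null(d$x, d$y, B = 200, seed = 1)
  expect_s3_class(ggplot2::autoplot(pr), "ggplot")
})
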