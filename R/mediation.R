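# Simple (single-mediator) covariate-adjusted mediation with bias-corrected
# bootstrap inference — the PROCESS model-4 structure: three OLS fits
#   M ~ X + covariates            (path a)
#   Y ~ X + M + covariates        (paths b and c')
#   Y ~ X + covariates            (total effect c)
# with indirect effect a*b and the OLS identity c = c' + a*b (same covariate
# set in all three equations). Inference on a*b uses case resampling with a
# bias-corrected percentile interval.

# One set of path fits on prepared design columns; returns NULL if any
# design is rank deficient (used to detect degenerate bootstrap resamples).
fit_paths_matrix <- function(xv, mv, yv, covs) {
  dm_m <- cbind(`(Intercept)` = 1, x = xv, covs)
  dm_y <- cbind(`(Intercept)` = 1, x = xv, m = mv, covs)
  f_a <- stats::.lm.fit(dm_m, mv)
  f_b <- stats::.lm.fit(dm_y, yv)
  f_c <- stats::.lm.fit(dm_m, yv)
  if (f_a$rank < ncol(dm_m) || f_b$rank < ncol(dm_y) || f_c$rank < ncol(dm_m)) {
    return(NULL)
  }
  list(a = f_a$coefficients[2], b = f_b$coefficients[3],
       c_prime = f_b$coefficients[2], c = f_c$coefficients[2],
       fits = list(a = f_a, b = f_b, c = f_c),
       dms = list(m = dm_m, y = dm_y))
}

ols_se <- function(fit, dm) {
  res <- fit$residuals
  df <- nrow(dm) - ncol(dm)
  sigma2 <- sum(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(dm)))
  sqrt(sigma2 * diag(xtxinv))
}

#' Fit the three mediation path regressions
#'
#' @param data Data frame containing the analysis columns.
#' @param x,m,y Column names of the independent variable, mediator and
#'   outcome.
#' @param covariates Covariate column names included in all three equations.
#' @param standardize If `TRUE` (default), x, m and y are z-scored before
#'   fitting, so paths are on the standardised scale.
#' @return A list with `a`, `b`, `c`, `c_prime`, `indirect = a * b`, their
#'   standard errors (`se_a`, `se_b`, `se_c`, `se_c_prime`), `n` and the
#'   `standardized` flag.
#' @export
fit_paths <- function(data, x, m, y, covariates = character(),
                      standardize = TRUE) {
  stopifnot(all(c(x, m, y, covariates) %in% names(data)),
            length(unique(c(x, m, y))) == 3L)
  d <- data[stats::complete.cases(data[, c(x, m, y, covariates)]), , drop = FALSE]
  z <- function(v) if (standardize) as.numeric(scale(v)) else as.numeric(v)
  xv <- z(d[[x]]); mv <- z(d[[m]]); yv <- z(d[[y]])
  covs <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else NULL
  fit <- fit_paths_matrix(xv, mv, yv, covs)
  if (is.null(fit)) {
    stop("rank-deficient design in mediation path fit (collinear columns among x, m and covariates)",
         call. = FALSE)
  }
  se_m <- ols_se(fit$fits$a, fit$dms$m)
  se_y <- ols_se(fit$fits$b, fit$dms$y)
  se_c <- ols_se(fit$fits$c, fit$dms$m)
  list(a = unname(fit$a), b = unname(fit$b), c = unname(fit$c),
       c_prime = unname(fit$c_prime), indirect = unname(fit$a * fit$b),
       se_a = se_m[2], se_b = se_y[3], se_c_prime = se_y[2], se_c = se_c[2],
       n = length(xv), standardized = standardize)
}

#' Bias-corrected bootstrap mediation
#'
#' Resamples subjects with replacement `n_boot` times, refits the paths,
#' collects the indirect effects a_k * b_k, and forms the bias-corrected
#' percentile interval: with z0 the normal quantile of the fraction of
#' bootstrap estimates below the point estimate, the bounds are the
#' bootstrap quantiles at Phi(2 z0 - z_(alpha/2)) and Phi(2 z0 +
#' z_(alpha/2)). The indirect effect is called significant when the interval
#' excludes zero. The same bias-corrected construction is applied to the
#' bootstrap distribution of the direct effect c', whose interval is the
#' package's inferential statement about the direct path: the case
#' bootstrap reflects the extra sampling variability that a measured
#' (noisy) mediator induces in c', which the OLS standard error
#' understates. Rank-deficient resamples are redrawn (their count is
#' reported); more than 10% degenerate draws aborts.
#'
#' @inheritParams fit_paths
#' @param n_boot Number of bootstrap resamples (>= 1000 for reported CIs).
#' @param alpha Interval level is `1 - alpha`.
#' @param seed Integer seed; fixed seed gives a fully reproducible interval.
#' @return An object of class `netmed_mediation`: the point estimates of
#'   [fit_paths()], `boot_indirects`, `ci_low`, `ci_high`, `significant`,
#'   the analogous interval for the direct effect (`boot_directs`,
#'   `ci_direct_low`, `ci_direct_high`, `direct_significant`), `n_boot`,
#'   `alpha`, `seed`, `n_redrawn`, and the variable names.
#' @export
bootstrap_indirect <- function(data, x, m, y, covariates = character(),
                               n_boot = 5000L, alpha = 0.05,
                               standardize = TRUE, seed = 1L) {
  est <- fit_paths(data, x, m, y, covariates, standardize = standardize)
  d <- data[stats::complete.cases(data[, c(x, m, y, covariates)]), , drop = FALSE]
  n <- nrow(d)
  if (n < 20) stop("mediation bootstrap needs at least 20 complete cases", call. = FALSE)
  if (n_boot < 1000) {
    warning("n_boot < 1000: confidence interval will be unstable", call. = FALSE)
  }
  z <- function(v) if (standardize) as.numeric(scale(v)) else as.numeric(v)
  xv <- z(d[[x]]); mv <- z(d[[m]]); yv <- z(d[[y]])
  covs <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else NULL

  boot <- numeric(n_boot)
  boot_direct <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (k in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        f <- fit_paths_matrix(xv[idx], mv[idx], yv[idx],
                              if (is.null(covs)) NULL else covs[idx, , drop = FALSE])
        if (!is.null(f)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * n_boot) {
          stop("more than 10% of bootstrap resamples were rank deficient; increase n",
               call. = FALSE)
        }
      }
      boot[k] <- f$a * f$b
      boot_direct[k] <- f$c_prime
    }
  })

  bc_ci <- function(draws, point) {
    frac_below <- mean(draws < point)
    frac_below <- min(max(frac_below, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z0 <- stats::qnorm(frac_below)
    zq <- stats::qnorm(1 - alpha / 2)
    unname(stats::quantile(draws, stats::pnorm(c(2 * z0 - zq, 2 * z0 + zq))))
  }
  ci <- bc_ci(boot, est$indirect)
  ci_d <- bc_ci(boot_direct, est$c_prime)

  structure(
    c(est,
      list(boot_indirects = boot, ci_low = ci[1], ci_high = ci[2],
           significant = ci[1] > 0 || ci[2] < 0,
           boot_directs = boot_direct,
           ci_direct_low = ci_d[1], ci_direct_high = ci_d[2],
           direct_significant = ci_d[1] > 0 || ci_d[2] < 0,
           n_boot = as.integer(n_boot), alpha = alpha, seed = as.integer(seed),
           n_redrawn = n_redrawn,
           x = x, m = m, y = y, covariates = covariates)),
    class = "netmed_mediation"
  )
}

#' @export
print.netmed_mediation <- function(x, ...) {
  cat(sprintf("<netmed_mediation> %s -> %s -> %s (covariates: %s)\n",
              x$x, x$m, x$y,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.3f, %d%% BC bootstrap CI (%.3f, %.3f)%s\n",
              x$indirect, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  cat(sprintf("  direct c' = %.3f, %d%% BC bootstrap CI (%.3f, %.3f)%s\n",
              x$c_prime, round(100 * (1 - x$alpha)), x$ci_direct_low,
              x$ci_direct_high, if (x$direct_significant) " *" else ""))
  invisible(x)
}

#' Run the mediation suite over regions (plus the education variant)
#'
#' Fits one covariate-adjusted mediation per region, with resilience as X,
#' the region's threshold-averaged metric as M and processing speed as Y,
#' and optionally the education-as-mediator variant (X resilience, M
#' education years, Y speed, covariates age and sex only).
#'
#' @param metric_tbl Region-level metric table from [region_metrics()].
#' @param phenotypes Phenotype tibble.
#' @param regions Mediator regions.
#' @param x,y Column names of the independent variable and outcome.
#' @param covariates Covariates for the region models.
#' @param metric Metric rows to use as mediators.
#' @param include_education If `TRUE`, adds the education-mediator model.
#' @param n_boot,alpha,standardize,seed Passed to [bootstrap_indirect()].
#' @return A tibble with one row per mediator: paths, indirect effect, BC
#'   CI, significance flag, and the fitted `netmed_mediation` objects in a
#'   list column `fit`.
#' @export
run_mediation_suite <- function(metric_tbl, phenotypes,
                                regions = c("Thalamus", "Hippocampus",
                                            "Caudate", "Insula"),
                                x = "resilience", y = "speed",
                                covariates = c("age", "sex", "education"),
                                metric = "degree",
                                include_education = TRUE,
                                n_boot = 5000L, alpha = 0.05,
                                standardize = TRUE, seed = 1L) {
  fits <- list()
  for (rg in regions) {
    d <- metric_tbl[metric_tbl$metric == metric & metric_tbl$region == rg,
                    c("subject_id", "value")] |>
      dplyr::inner_join(phenotypes, by = "subject_id")
    fits[[rg]] <- bootstrap_indirect(
      d, x = x, m = "value", y = y, covariates = covariates,
      n_boot = n_boot, alpha = alpha, standardize = standardize,
      seed = derive_seed(seed, paste0("med-", rg))
    )
    fits[[rg]]$m <- paste0(metric, "[", rg, "]")
  }
  if (include_education) {
    fits[["education"]] <- bootstrap_indirect(
      phenotypes, x = x, m = "education", y = y,
      covariates = setdiff(covariates, "education"),
      n_boot = n_boot, alpha = alpha, standardize = standardize,
      seed = derive_seed(seed, "med-education")
    )
  }
  purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(
      mediator = nm, x = f$x, m = f$m, y = f$y,
      covariates = paste(f$covariates, collapse = ","),
      n = f$n, a = f$a, b = f$b, c = f$c, c_prime = f$c_prime,
      indirect = f$indirect, ci_low = f$ci_low, ci_high = f$ci_high,
      significant = f$significant,
      ci_direct_low = f$ci_direct_low, ci_direct_high = f$ci_direct_high,
      direct_significant = f$direct_significant, n_boot = f$n_boot,
      standardized = f$standardized, seed = f$seed,
      fit = list(f)
    )
  })
}
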