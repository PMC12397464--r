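# Covariate-adjusted rank-correlation inference: partial Spearman
# coefficients (rank, residualise, correlate), Benjamini-Hochberg FDR across
# the screened regions, and seeded outcome-permutation null distributions.

rank_avg <- function(x) rank(x, ties.method = "average")

# Residualise the columns of `y` (matrix or vector) on [1 | covs].
resid_on <- function(y, covs = NULL) {
  n <- NROW(y)
  x <- if (is.null(covs) || NCOL(covs) == 0L) matrix(1, n, 1) else cbind(1, covs)
  qr.resid(qr(x), as.matrix(y))
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and every covariate column (average ranks on ties),
#' residualises the x- and y-ranks on an intercept plus the covariate ranks,
#' and correlates the residuals. The p-value uses the t approximation with
#' n - 2 - k degrees of freedom (k covariates), two-sided. With no
#' covariates this is the ordinary Spearman correlation.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param x_name,y_name Labels carried into the result.
#' @return A one-row tibble: `x_name`, `y_name`, `covariates`, `n`, `rho`,
#'   `statistic`, `df`, `p`.
#' @export
#' @examples
#' x <- rnorm(30); y <- exp(x)                # strictly monotone
#' partial_spearman(x, y)$rho                 # 1
partial_spearman <- function(x, y, covariates = NULL,
                             x_name = "x", y_name = "y") {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  covariates <- prep_covariates(covariates, n)
  k <- NCOL2(covariates)
  if (n < k + 4) stop("too few observations for the covariate count", call. = FALSE)
  rx <- rank_avg(x); ry <- rank_avg(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("degenerate variable: constant after ranking", call. = FALSE)
  }
  rc <- if (is.null(covariates)) NULL else apply(covariates, 2, rank_avg)
  ex <- resid_on(rx, rc); ey <- resid_on(ry, rc)
  rho <- as.numeric(stats::cor(ex, ey))
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(
    x_name = x_name, y_name = y_name,
    covariates = paste(colnames(covariates) %||% character(), collapse = ","),
    n = n, rho = rho, statistic = tstat, df = df, p = min(1, p)
  )
}

prep_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) == 0L) return(NULL)
  stopifnot(nrow(covariates) == n, !anyNA(covariates))
  covariates
}

NCOL2 <- function(x) if (is.null(x)) 0L else ncol(x)

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment: q(i) = min over j with p(j) >=
#' p(i) of m * p(j) / rank(j), capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
#' @examples
#' fdr_bh(c(0.004, 0.021, 0.002, 0.478))   # 0.008 0.028 0.008 0.478
fdr_bh <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation null distribution for a partial Spearman correlation
#'
#' Shuffles the outcome y (B times, seeded) while keeping x and the
#' covariates aligned, recomputes the partial Spearman coefficient for each
#' shuffle, and returns the two-sided add-one empirical p-value
#' (1 + #{|rho_b| >= |rho_obs|}) / (B + 1). Only the outcome is permuted, so
#' the covariate structure of the predictors is preserved.
#'
#' @inheritParams partial_spearman
#' @param B Number of permutations.
#' @param seed Integer seed; fixed seed gives identical null draws.
#' @return A list of class `netmed_perm`: `observed_rho`, `null_rhos`
#'   (length B), `empirical_p`, `B`, `seed`.
#' @export
permutation_null <- function(x, y, covariates = NULL, B = 5000L, seed = 1L) {
  if (B < 100) warning("B < 100 gives a very coarse empirical p-value", call. = FALSE)
  n <- length(x)
  covariates <- prep_covariates(covariates, n)
  obs <- partial_spearman(x, y, covariates)$rho
  rc <- if (is.null(covariates)) NULL else apply(covariates, 2, rank_avg)
  ex <- resid_on(rank_avg(x), rc)
  ry <- rank_avg(y)
  xq <- qr(if (is.null(rc)) matrix(1, n, 1) else cbind(1, rc))
  null_rhos <- with_seed(seed, {
    perms <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    yp <- matrix(ry[perms], n, B)
    ep <- qr.resid(xq, yp)
    as.numeric(stats::cor(ex, ep))
  })
  structure(
    list(observed_rho = obs, null_rhos = null_rhos,
         empirical_p = (1 + sum(abs(null_rhos) >= abs(obs))) / (B + 1),
         B = as.integer(B), seed = as.integer(seed)),
    class = "netmed_perm"
  )
}

#' @export
print.netmed_perm <- function(x, ...) {
  cat(sprintf("<netmed_perm> observed rho = %.3f, empirical p = %.4g (B = %d, seed %d)\n",
              x$observed_rho, x$empirical_p, x$B, x$seed))
  invisible(x)
}

#' Screen regions for metric-behaviour associations
#'
#' For each region (or every ROI with `regions = "all"`), computes the
#' covariate-adjusted partial Spearman correlation between the region's
#' threshold-averaged metric and an outcome, then adjusts across exactly the
#' screened set with Benjamini-Hochberg FDR. Optionally adds a seeded
#' permutation p-value per region.
#'
#' @param metric_tbl Long metric table (columns `subject_id`, `metric`,
#'   `region` or `roi`, `value`), e.g. from [region_metrics()].
#' @param phenotypes Phenotype tibble with `subject_id`, the outcome column
#'   and the covariate columns; joined to the metrics on `subject_id`.
#' @param outcome Name of the outcome column (e.g. `"speed"`).
#' @param covariates Names of covariate columns (default age, sex,
#'   education).
#' @param regions Regions to screen in output order, or `"all"` for every
#'   distinct region/ROI present.
#' @param metric Which metric rows to use.
#' @param B If non-zero, permutations per region for an empirical p-value.
#' @param seed Seed for the permutation nulls.
#' @param min_n Minimum joined sample size.
#' @return A tibble of class `netmed_screen`: one row per region with `rho`,
#'   `p`, `q` and optionally `empirical_p`.
#' @export
roi_association_screen <- function(metric_tbl, phenotypes, outcome,
                                   covariates = c("age", "sex", "education"),
                                   regions = c("Thalamus", "Hippocampus",
                                               "Caudate", "Insula"),
                                   metric = "degree",
                                   B = 0L, seed = 1L, min_n = 10L) {
  unit_col <- if ("region" %in% names(metric_tbl)) "region" else "roi"
  stopifnot(all(c("subject_id", "metric", unit_col, "value") %in% names(metric_tbl)),
            all(c("subject_id", outcome, covariates) %in% names(phenotypes)))
  tbl <- metric_tbl[metric_tbl$metric == metric, , drop = FALSE]
  if (identical(regions, "all")) regions <- unique(tbl[[unit_col]])
  stopifnot(length(regions) >= 1)

  res <- purrr::map_dfr(regions, function(rg) {
    d <- tbl[tbl[[unit_col]] == rg, c("subject_id", "value")] |>
      dplyr::inner_join(phenotypes, by = "subject_id")
    if (nrow(d) < min_n) {
      stop(sprintf("region '%s': only %d subjects after joining metrics and phenotypes",
                   rg, nrow(d)), call. = FALSE)
    }
    covs <- as.matrix(d[, covariates, drop = FALSE])
    out <- partial_spearman(d$value, d[[outcome]], covs,
                            x_name = rg, y_name = outcome)
    out$metric <- metric
    if (B > 0) {
      out$empirical_p <- permutation_null(
        d$value, d[[outcome]], covs, B = B,
        seed = derive_seed(seed, paste0("perm-", rg))
      )$empirical_p
      out$B <- as.integer(B)
    }
    out
  })
  res <- dplyr::rename(res, region = "x_name", outcome = "y_name")
  res$q <- fdr_bh(res$p)
  class(res) <- c("netmed_screen", class(res))
  res
}
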