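# Synthetic cohort with a planted mediation. The generator is the test-bed
# for the whole pipeline: behaviour (processing speed) is driven by a latent
# per-subject variable u that also modulates the covariance of one target
# region's time series, so the planted indirect effect maps directly onto
# degree centrality and is analytically checkable from the covariance.
#
# Generative model (all effects on standardised scales):
#   resilience  X_i  ~  N(28.4, 5.63^2) truncated to [0, 45]
#   latent      u_i  =  path_a * z(X_i) + e_u,            e_u ~ N(0, sd_latent)
#   modulation  d_i  =  modulation_gain * 1.5 tanh(u_i/1.5)  (soft-clipped; scales target cov rows)
#   speed       Y_i  =  path_b * u_i + path_c_prime * z(X_i)
#                       + beta_age z(age) + beta_edu z(edu) + beta_sex sex
#                       + e_y,                            e_y ~ N(0, sd_speed)
# then mapped to the SDMT scale (mean 53.9, SD 10.7) and rounded.
# With path_a < 0 and path_b < 0, higher resilience means lower target-region
# connectivity, lower connectivity means slower processing speed, and the
# indirect effect a*b is positive — the qualitative pattern the pipeline is
# designed to detect.

#' Ground-truth parameters for a synthetic cohort
#'
#' Bundles the planted path coefficients, covariate effects, noise scales and
#' network parameters that define a synthetic study. The defaults emulate a
#' cohort of 101 community-dwelling older adults (ages 60-79) with a full
#' mediation of the resilience-speed association through the bilateral
#' thalamus: `path_a = -0.5` (resilience lowers target connectivity),
#' `path_b = -0.4` (lower connectivity, faster speed — equivalently higher
#' connectivity predicts slower speed), and `path_c_prime = -0.05`. The
#' small negative latent direct path makes the cohort emulate observed full
#' mediation: estimated degree centrality measures the latent with error
#' (proxy correlation about 0.9 under the default dimensions), which biases
#' the observable direct effect upward by roughly a*b(1 - lambda^2) /
#' (1 - lambda^2 a^2), about +0.05 here; the offset centres the observable
#' direct effect at zero, the pattern the pipeline is designed to detect.
#'
#' @param path_a Latent-on-resilience path (standardised).
#' @param path_b Speed-on-latent path (standardised).
#' @param path_c_prime Direct resilience-on-speed path (standardised).
#' @param modulation_gain Scale from latent u to the covariance modulation of
#'   the target region's rows.
#' @param covariate_effects Named vector of standardised effects of age, sex
#'   and education on speed.
#' @param noise_sds Named vector: `latent` (SD of e_u) and `speed` (SD of e_y).
#' @param target_roi Bilateral region whose connectivity carries the planted
#'   effect; must be a `region` of the atlas.
#' @param base_correlation Common off-diagonal correlation of the unmodulated
#'   ROI covariance, in (0, 1).
#' @param ar_coefficient Lag-1 temporal autocorrelation of the simulated BOLD
#'   series (innovation-level AR(1) coefficient).
#' @param spike_probability Per-volume probability of a motion spike.
#' @param seed Integer seed that fully determines all draws.
#' @return A list of class `netmed_truth`.
#' @export
ground_truth <- function(path_a = -0.5,
                         path_b = -0.4,
                         path_c_prime = -0.05,
                         modulation_gain = 0.44,
                         covariate_effects = c(age = -0.2, sex = 0, education = 0.3),
                         noise_sds = c(latent = 0.8, speed = 0.6),
                         target_roi = "Thalamus",
                         base_correlation = 0.3,
                         ar_coefficient = 0.3,
                         spike_probability = 0.005,
                         seed = 1L) {
  stopifnot(
    base_correlation > 0, base_correlation < 1,
    ar_coefficient >= 0, ar_coefficient < 1,
    spike_probability >= 0, spike_probability <= 1,
    all(noise_sds >= 0)
  )
  structure(
    list(
      path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
      modulation_gain = modulation_gain,
      covariate_effects = covariate_effects,
      noise_sds = noise_sds,
      target_roi = target_roi,
      base_correlation = base_correlation,
      ar_coefficient = ar_coefficient,
      spike_probability = spike_probability,
      seed = as.integer(seed),
      subject_latent = NULL
    ),
    class = "netmed_truth"
  )
}

#' One subject's ROI time series
#'
#' @param data Numeric matrix, volumes by ROIs.
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time in seconds.
#' @param roi_names Optional ROI labels (defaults to column names).
#' @return An object of class `netmed_ts`.
#' @export
subject_timeseries <- function(data, subject_id, tr_seconds = 2,
                               roi_names = colnames(data)) {
  assert_matrix(data, "data")
  if (nrow(data) < 2L) stop("time series needs at least 2 volumes", call. = FALSE)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(data)))
  stopifnot(length(roi_names) == ncol(data), tr_seconds > 0)
  colnames(data) <- roi_names
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_seconds = tr_seconds, roi_names = roi_names),
    class = "netmed_ts"
  )
}

#' @export
print.netmed_ts <- function(x, ...) {
  cat(sprintf("<netmed_ts> subject %s: %d volumes x %d ROIs, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Build a modulated ROI covariance matrix
#'
#' Constructs a compound-symmetry correlation matrix (unit diagonal, constant
#' off-diagonal `base_correlation`) and scales every off-diagonal entry that
#' touches a target ROI by `(1 + modulation)`. Entries are clipped into
#' (-0.99, 0.99) and, if needed, the matrix is shrunk toward the identity
#' until it is positive definite.
#'
#' @param n_rois Number of ROIs (at least 3).
#' @param base_correlation Common off-diagonal correlation.
#' @param target_roi Integer index (or indices, e.g. both hemisphere nodes of
#'   a bilateral region) of the modulated ROI.
#' @param modulation Relative scaling of the target's off-diagonal entries.
#' @return A symmetric positive-definite `n_rois` x `n_rois` matrix with unit
#'   diagonal.
#' @export
#' @examples
#' S <- make_covariance(4, 0.3, target_roi = 1, modulation = 0.5)
#' S[1, -1]  # 0.45
make_covariance <- function(n_rois, base_correlation, target_roi, modulation) {
  stopifnot(n_rois >= 3, all(target_roi >= 1), all(target_roi <= n_rois))
  s <- matrix(base_correlation, n_rois, n_rois)
  diag(s) <- 1
  touch <- rep(FALSE, n_rois)
  touch[target_roi] <- TRUE
  scale_mask <- outer(touch, touch, `|`)
  diag(scale_mask) <- FALSE
  s[scale_mask] <- s[scale_mask] * (1 + modulation)
  off <- row(s) != col(s)
  s[off] <- pmin(pmax(s[off], -0.99), 0.99)
  s <- (s + t(s)) / 2
  for (lambda in seq(0, 0.5, by = 0.01)) {
    shrunk <- (1 - lambda) * s + lambda * diag(n_rois)
    if (min(eigen(shrunk, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
      return(shrunk)
    }
  }
  stop("covariance not positive definite after maximum shrinkage toward identity",
       call. = FALSE)
}

#' Simulate a stationary multivariate AR(1) ROI time series
#'
#' Draws a zero-mean series whose innovation covariance is `cov` and whose
#' lag-1 temporal autocorrelation is approximately `ar_coefficient` (one
#' common AR(1) coefficient across ROIs, so the cross-ROI correlation
#' structure of the stationary distribution equals that of `cov`). The first
#' volume is drawn from the stationary distribution, so no burn-in is needed.
#'
#' @param cov Positive-definite innovation covariance (ROIs x ROIs).
#' @param n_volumes Number of volumes to simulate.
#' @param ar_coefficient AR(1) coefficient in [0, 1).
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @param tr_seconds Repetition time stored on the result.
#' @param subject_id Identifier stored on the result.
#' @return A [subject_timeseries()] object.
#' @export
simulate_timeseries <- function(cov, n_volumes, ar_coefficient = 0.3, seed = 1L,
                                tr_seconds = 2, subject_id = "sim") {
  assert_matrix(cov, "cov")
  stopifnot(nrow(cov) == ncol(cov), ar_coefficient >= 0, ar_coefficient < 1,
            n_volumes >= 2)
  n_rois <- nrow(cov)
  if (n_volumes < 10 * n_rois) {
    warning(sprintf(
      "n_volumes (%d) < 10 x n_rois (%d): subject-level correlation estimates will be noisy",
      n_volumes, n_rois), call. = FALSE)
  }
  ch <- chol(cov)
  x <- with_seed(seed, {
    e <- matrix(stats::rnorm(n_volumes * n_rois), n_volumes, n_rois) %*% ch
    out <- e
    out[1, ] <- e[1, ] / sqrt(1 - ar_coefficient^2)
    if (ar_coefficient > 0) {
      for (t in 2:n_volumes) out[t, ] <- ar_coefficient * out[t - 1, ] + e[t, ]
    }
    out
  })
  subject_timeseries(x, subject_id = subject_id, tr_seconds = tr_seconds)
}

#' Generate phenotypes with a planted mediation chain
#'
#' Draws the behavioural and demographic table: resilience truncated-normal
#' on its 0-45 scale (mean 28.4, SD 5.63), age uniform on 60-79, sex coded
#' 1 = female with the 73/101 cohort proportion, education truncated-normal
#' (mean 12.2, SD 4.67, non-negative), screening scores that pass the
#' cognitive/depression criteria, and processing speed generated from the
#' latent chain described in [ground_truth()] on the SDMT scale (mean 53.9,
#' SD 10.7, rounded to a non-negative integer).
#'
#' @param truth A [ground_truth()] object.
#' @param n_subjects Number of subjects (at least 10).
#' @param seed Integer seed.
#' @return A list: `phenotypes` (tibble), `latent` (u per subject) and
#'   `modulation` (covariance modulation per subject).
#' @export
generate_phenotypes <- function(truth, n_subjects = 101, seed = truth$seed) {
  stopifnot(inherits(truth, "netmed_truth"), n_subjects >= 10)
  ce <- truth$covariate_effects
  with_seed(seed, {
    resilience <- round(rtruncnorm(n_subjects, 28.4, 5.63, 0, 45))
    age <- stats::runif(n_subjects, 60, 79)
    sex <- stats::rbinom(n_subjects, 1, 73 / 101) # 1 = female
    education <- round(rtruncnorm(n_subjects, 12.2, 4.67, 0, Inf), 1)
    moca <- pmin(30L, pmax(22L, round(rtruncnorm(n_subjects, 26.5, 2, 22, 30))))
    gds <- pmin(7L, stats::rpois(n_subjects, 2))

    zx <- as.numeric(scale(resilience))
    u <- truth$path_a * zx + stats::rnorm(n_subjects, 0, truth$noise_sds[["latent"]])
    speed_std <- truth$path_b * u + truth$path_c_prime * zx +
      ce[["age"]] * as.numeric(scale(age)) +
      ce[["education"]] * as.numeric(scale(education)) +
      ce[["sex"]] * sex +
      stats::rnorm(n_subjects, 0, truth$noise_sds[["speed"]])
    speed <- pmax(0, round(53.9 + 10.7 * speed_std))

    list(
      phenotypes = tibble::tibble(
        subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
        age = round(age, 1), sex = sex, education = education,
        resilience = as.integer(resilience), speed = as.integer(speed),
        moca = as.integer(moca), gds = as.integer(gds)
      ),
      latent = u,
      # soft-clipped monotone map: near-linear over typical draws (|u| < 1.5)
      # but bounded at 1.5 * gain, keeping the modulated covariance positive
      # definite for extreme latent draws
      modulation = truth$modulation_gain * 1.5 * tanh(u / 1.5)
    )
  })
}

#' Generate motion parameters and tissue signals for one subject
#'
#' Motion is a mean-reverting random walk in six dimensions (three
#' translations in mm, three rotations in radians) with occasional large
#' spikes on a random translation axis; tissue signals (white matter, CSF,
#' global) are smooth low-frequency series. A spike produces a single
#' framewise-displacement exceedance, so the expected number of flagged
#' volumes before neighbour expansion is about `(n_volumes - 1) *
#' spike_probability`.
#'
#' @param n_volumes Number of volumes.
#' @param spike_probability Per-volume spike probability in [0, 1].
#' @param seed Integer seed.
#' @param step_sd_translation,step_sd_rotation Innovation SDs of the walk
#'   (mm, radians).
#' @param spike_range Range of spike magnitudes in mm.
#' @return A list of class `netmed_confounds` with `motion6` (volumes x 6)
#'   and `tissue_signals` (volumes x 3: wm, csf, global).
#' @export
generate_motion <- function(n_volumes, spike_probability = 0.005, seed = 1L,
                            step_sd_translation = 0.02,
                            step_sd_rotation = 2e-4,
                            spike_range = c(0.55, 0.9)) {
  stopifnot(spike_probability >= 0, spike_probability <= 1, n_volumes >= 2)
  with_seed(seed, {
    steps <- cbind(
      matrix(stats::rnorm(n_volumes * 3, 0, step_sd_translation), n_volumes, 3),
      matrix(stats::rnorm(n_volumes * 3, 0, step_sd_rotation), n_volumes, 3)
    )
    # spikes: impulse on one translation axis; FD picks up the jump once
    spike_at <- which(stats::runif(n_volumes) < spike_probability)
    spike_at <- spike_at[spike_at > 1]
    for (t in spike_at) {
      axis <- sample.int(3, 1)
      steps[t, axis] <- steps[t, axis] +
        sample(c(-1, 1), 1) * stats::runif(1, spike_range[1], spike_range[2])
    }
    motion6 <- matrix(0, n_volumes, 6)
    for (t in 2:n_volumes) motion6[t, ] <- 0.95 * motion6[t - 1, ] + steps[t, ]
    colnames(motion6) <- c("trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z")

    t_sec <- seq_len(n_volumes)
    tissue <- vapply(c("wm", "csf", "global"), function(nm) {
      freqs <- stats::runif(3, 0.005, 0.03)
      amps <- stats::rnorm(3, 0, 1)
      phases <- stats::runif(3, 0, 2 * pi)
      rowSums(vapply(1:3, function(k) {
        amps[k] * sin(2 * pi * freqs[k] * t_sec * 2 + phases[k])
      }, numeric(n_volumes))) + stats::rnorm(n_volumes, 0, 0.1)
    }, numeric(n_volumes))
    structure(
      list(motion6 = motion6, tissue_signals = tissue,
           spike_volumes = spike_at),
      class = "netmed_confounds"
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates phenotypes, per-subject modulated covariances, ROI time series,
#' and motion/tissue confounds for a cohort with a planted mediation of
#' processing speed through the target region's connectivity. Default
#' dimensions are 101 subjects, 90 ROIs and 240 volumes at TR = 2 s (235
#' analysed after the initial discard).
#'
#' @param n_subjects,n_rois,n_volumes Cohort dimensions.
#' @param truth A [ground_truth()] object; its `seed` is overridden by `seed`
#'   when given.
#' @param seed Master seed for the cohort (defaults to the truth's seed).
#' @param atlas Atlas label table; the truth's `target_roi` must be one of
#'   its regions.
#' @return A list of class `netmed_cohort`: `timeseries` (list of
#'   [subject_timeseries()]), `confounds`, `phenotypes`, `truth` (with the
#'   realised `subject_latent` and `modulation` filled in) and `atlas`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_subjects = 10, n_rois = 10, n_volumes = 60, seed = 7)
#' coh$phenotypes
simulate_cohort <- function(n_subjects = 101, n_rois = 90, n_volumes = 240,
                            truth = ground_truth(), seed = truth$seed,
                            atlas = default_atlas()) {
  stopifnot(inherits(truth, "netmed_truth"))
  truth$seed <- as.integer(seed)
  atlas <- atlas[atlas$index <= n_rois, , drop = FALSE]
  if (truth$target_roi %in% atlas$region) {
    target_idx <- unname(region_indices(atlas, truth$target_roi))
  } else {
    # small test cohorts without the named region: plant on the first ROI
    target_idx <- 1L
  }

  phen <- generate_phenotypes(truth, n_subjects, seed = derive_seed(seed, "phenotypes"))
  truth$subject_latent <- phen$latent
  truth$modulation <- phen$modulation

  ids <- phen$phenotypes$subject_id
  roi_names <- if (nrow(atlas) == n_rois) atlas$name else paste0("ROI", seq_len(n_rois))

  timeseries <- vector("list", n_subjects)
  confounds <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- make_covariance(n_rois, truth$base_correlation, target_idx,
                         phen$modulation[i])
    ts <- suppressWarnings(simulate_timeseries(
      s, n_volumes, truth$ar_coefficient,
      seed = derive_seed(seed, paste0("ts-", i)),
      subject_id = ids[i]
    ))
    colnames(ts$data) <- roi_names
    ts$roi_names <- roi_names
    timeseries[[i]] <- ts
    confounds[[i]] <- generate_motion(
      n_volumes, truth$spike_probability,
      seed = derive_seed(seed, paste0("motion-", i))
    )
  }
  structure(
    list(timeseries = timeseries, confounds = confounds,
         phenotypes = phen$phenotypes, truth = truth, atlas = atlas),
    class = "netmed_cohort"
  )
}

#' @export
print.netmed_cohort <- function(x, ...) {
  cat(sprintf(
    "<netmed_cohort> %d subjects x %d ROIs x %d volumes (target region: %s, seed %d)\n",
    length(x$timeseries), ncol(x$timeseries[[1]]$data),
    nrow(x$timeseries[[1]]$data), x$truth$target_roi, x$truth$seed))
  invisible(x)
}
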