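# Temporal preprocessing of ROI time series and cohort-level QC. The fixed
# cleaning order is: initial-volume discard -> framewise displacement and
# spike regressors -> joint nuisance regression (tissue + global + Friston-24
# + spikes) -> band-pass. All operations are deterministic.

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes (signal equilibration / scanner
#' adaptation period). With the default 5, a 240-volume scan keeps 235.
#'
#' @param ts A [subject_timeseries()] object.
#' @param n_discard Number of leading volumes to drop.
#' @return A [subject_timeseries()] with the leading rows removed.
#' @export
discard_initial <- function(ts, n_discard = 5L) {
  stopifnot(inherits(ts, "netmed_ts"), n_discard >= 0)
  if (n_discard >= nrow(ts$data)) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, nrow(ts$data)),
         call. = FALSE)
  }
  if (n_discard == 0L) return(ts)
  ts$data <- ts$data[-seq_len(n_discard), , drop = FALSE]
  ts
}

#' Framewise displacement from six rigid-body motion parameters
#'
#' Power-style FD: the L1 norm of the backward differences of the six
#' realignment parameters, with rotations (radians) converted to arc length
#' on a sphere of radius `rotation_radius_mm`. The first volume has FD 0 by
#' convention.
#'
#' @param motion6 Numeric matrix, volumes x 6 (translations mm, rotations
#'   radians, in that column order).
#' @param rotation_radius_mm Sphere radius for the rotation arc length.
#' @return Numeric vector of per-volume FD values (mm), `fd[1] = 0`.
#' @export
#' @examples
#' m <- matrix(0, 10, 6); m[6, 1] <- 1   # 1 mm step at volume 6
#' framewise_displacement(m)[6]          # 1
framewise_displacement <- function(motion6, rotation_radius_mm = 50) {
  assert_matrix(motion6, "motion6")
  stopifnot(ncol(motion6) == 6, nrow(motion6) >= 2)
  d <- diff(motion6)
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    rotation_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]))
  c(0, fd)
}

#' Spike (scrubbing) regressors from framewise displacement
#'
#' Flags every volume whose FD exceeds `threshold_mm`, together with
#' `n_before` volumes before and `n_after` volumes after it (defaults: one
#' before, two after), and returns one unit-impulse indicator column per
#' flagged volume, for use as censoring covariates in the nuisance
#' regression.
#'
#' @param fd Per-volume FD vector.
#' @param threshold_mm FD threshold in mm.
#' @param n_before,n_after Neighbour volumes to flag around each exceedance.
#' @return Numeric matrix, volumes x number of flagged volumes (zero columns
#'   when nothing is flagged), with the flagged volume indices as column
#'   names.
#' @export
build_scrub_regressors <- function(fd, threshold_mm = 0.5, n_before = 1L,
                                   n_after = 2L) {
  stopifnot(length(fd) >= 1, all(is.finite(fd)))
  n <- length(fd)
  exceed <- which(fd > threshold_mm)
  flagged <- sort(unique(unlist(lapply(exceed, function(t) {
    (t - n_before):(t + n_after)
  }))))
  flagged <- flagged[flagged >= 1 & flagged <= n]
  out <- matrix(0, n, length(flagged))
  for (j in seq_along(flagged)) out[flagged[j], j] <- 1
  colnames(out) <- as.character(flagged)
  out
}

#' Friston 24-parameter motion expansion
#'
#' Expands six realignment parameters into the 24-regressor set: the six
#' parameters, their backward differences (first row zero), and the squares
#' of both blocks, in that fixed column order.
#'
#' @param motion6 Numeric matrix, volumes x 6.
#' @return Numeric matrix, volumes x 24.
#' @export
expand_friston24 <- function(motion6) {
  assert_matrix(motion6, "motion6")
  stopifnot(ncol(motion6) == 6, nrow(motion6) >= 2)
  d <- rbind(rep(0, 6), diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("dm", 1:6),
                     paste0("m", 1:6, "_sq"), paste0("dm", 1:6, "_sq"))
  out
}

#' Regress confounds out of ROI time series
#'
#' Replaces each ROI column by its least-squares residual against an
#' intercept plus the supplied confound columns. Exactly collinear confound
#' columns are dropped (pivoted QR); residuals are orthogonal to every
#' retained column.
#'
#' @param ts A [subject_timeseries()] object.
#' @param confounders Numeric matrix with one row per volume (may have zero
#'   columns for a plain demean).
#' @return A [subject_timeseries()] holding the residual series.
#' @export
regress_confounds <- function(ts, confounders = NULL) {
  stopifnot(inherits(ts, "netmed_ts"))
  n <- nrow(ts$data)
  if (is.null(confounders) || ncol(as.matrix(confounders)) == 0L) {
    x <- matrix(1, n, 1)
  } else {
    confounders <- as.matrix(confounders)
    assert_matrix(confounders, "confounders")
    if (nrow(confounders) != n) {
      stop(sprintf("confounders have %d rows but time series has %d volumes",
                   nrow(confounders), n), call. = FALSE)
    }
    x <- cbind(1, confounders)
  }
  if (ncol(x) >= n) {
    stop(sprintf(
      "design has %d columns for %d volumes; reduce the number of confound regressors",
      ncol(x), n), call. = FALSE)
  }
  qx <- qr(x)
  ts$data <- qr.resid(qx, ts$data)
  ts
}

#' Band-pass filter ROI time series
#'
#' Zero-phase ideal (rectangular frequency response) band-pass: each column
#' is demeaned, transformed to the frequency domain, components outside
#' `[low_hz, high_hz]` are zeroed, and the series is transformed back. This
#' is the convention of the standard resting-state toolchains; the DC
#' component always lies outside the pass band, so constant series map to
#' (numerical) zero.
#'
#' @param ts A [subject_timeseries()] object.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 * tr_seconds)`.
#' @return A filtered [subject_timeseries()].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "netmed_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency %g Hz (TR = %g s)",
                 high_hz, nyquist, ts$tr_seconds), call. = FALSE)
  }
  n <- nrow(ts$data)
  freqs <- (seq_len(n) - 1) / (n * ts$tr_seconds)
  freqs <- pmin(freqs, 1 / ts$tr_seconds - freqs) # two-sided bin frequencies
  keep <- freqs >= low_hz & freqs <= high_hz
  x <- scale(ts$data, center = TRUE, scale = FALSE)
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0 + 0i
  ts$data <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  dimnames(ts$data) <- list(NULL, ts$roi_names)
  ts
}

#' Clean one subject's time series
#'
#' Applies the full per-subject cleaning chain in the fixed order: discard
#' initial volumes (from the series and the confounds), compute FD, build
#' spike regressors for FD exceedances, jointly regress out tissue/global
#' signals, the Friston-24 expansion and the spikes, then band-pass filter.
#'
#' @param ts A [subject_timeseries()] object (raw, including the initial
#'   volumes).
#' @param confounds A `netmed_confounds` object (or a list with `motion6` and
#'   optionally `tissue_signals`) with one row per raw volume.
#' @param n_discard Leading volumes to drop.
#' @param fd_threshold_mm Scrubbing threshold on per-volume FD.
#' @param low_hz,high_hz Band-pass edges.
#' @return A list: `ts` (cleaned series), `fd` (post-discard FD vector),
#'   `n_scrubbed` (number of flagged volumes), `mean_fd`, and motion maxima
#'   used by QC (`max_abs_translation_mm`, `max_abs_rotation_deg`).
#' @export
clean_timeseries <- function(ts, confounds, n_discard = 5L,
                             fd_threshold_mm = 0.5,
                             low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "netmed_ts"))
  motion6 <- confounds$motion6
  if (nrow(motion6) != nrow(ts$data)) {
    stop("motion parameters and time series have different volume counts",
         call. = FALSE)
  }
  keep <- if (n_discard > 0L) -seq_len(n_discard) else TRUE
  ts <- discard_initial(ts, n_discard)
  motion6 <- motion6[keep, , drop = FALSE]
  tissue <- confounds$tissue_signals
  if (!is.null(tissue)) tissue <- as.matrix(tissue)[keep, , drop = FALSE]

  fd <- framewise_displacement(motion6)
  spikes <- build_scrub_regressors(fd, threshold_mm = fd_threshold_mm)
  nuisance <- cbind(tissue, expand_friston24(motion6), spikes)
  ts <- regress_confounds(ts, nuisance)
  ts <- bandpass(ts, low_hz, high_hz)

  list(
    ts = ts,
    fd = fd,
    n_scrubbed = ncol(spikes),
    mean_fd = mean(fd),
    max_abs_translation_mm = max(abs(motion6[, 1:3])),
    max_abs_rotation_deg = max(abs(motion6[, 4:6])) * 180 / pi
  )
}

#' Cohort-level quality-control filter
#'
#' Applies the inclusion rules: cognitively unimpaired (MoCA >= 22), not
#' depressed (GDS <= 7), and minimal head motion. The motion rule has two
#' readings: the default `"conjunction"` requires all three bounds (absolute
#' translation <= 2 mm AND rotation <= 2 degrees AND mean FD <= 0.2 mm);
#' `"disjunction"` accepts either the absolute bounds or the mean-FD bound.
#' All bounds are inclusive. Subjects with missing fields are excluded with
#' reason `"missing-data"`.
#'
#' @param reports A data frame with one row per subject and columns
#'   `subject_id`, `max_abs_translation_mm`, `max_abs_rotation_deg`,
#'   `mean_fd`, `moca`, `gds`.
#' @param motion_rule `"conjunction"` (default) or `"disjunction"`.
#' @param max_translation_mm,max_rotation_deg,max_mean_fd,min_moca,max_gds
#'   Inclusion bounds.
#' @return A tibble: the input columns plus `included` (logical) and
#'   `reasons` (semicolon-separated exclusion reasons, `""` when included).
#' @export
qc_filter <- function(reports, motion_rule = c("conjunction", "disjunction"),
                      max_translation_mm = 2, max_rotation_deg = 2,
                      max_mean_fd = 0.2, min_moca = 22, max_gds = 7) {
  motion_rule <- match.arg(motion_rule)
  reports <- tibble::as_tibble(reports)
  needed <- c("subject_id", "max_abs_translation_mm", "max_abs_rotation_deg",
              "mean_fd", "moca", "gds")
  missing_cols <- setdiff(needed, names(reports))
  if (length(missing_cols) > 0) {
    stop("QC input lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  one <- function(row) {
    vals <- row[needed[-1]]
    if (anyNA(unlist(vals))) return("missing-data")
    reasons <- character()
    if (row$moca < min_moca) reasons <- c(reasons, "cognitive-screen")
    if (row$gds > max_gds) reasons <- c(reasons, "depression-screen")
    abs_ok <- row$max_abs_translation_mm <= max_translation_mm &&
      row$max_abs_rotation_deg <= max_rotation_deg
    fd_ok <- row$mean_fd <= max_mean_fd
    motion_ok <- if (motion_rule == "conjunction") abs_ok && fd_ok else abs_ok || fd_ok
    if (!motion_ok) reasons <- c(reasons, "head-motion")
    paste(reasons, collapse = ";")
  }
  reports$reasons <- vapply(seq_len(nrow(reports)),
                            function(i) one(reports[i, ]), character(1))
  reports$included <- reports$reasons == ""
  reports
}
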