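# Subject-level functional-connectivity networks: Pearson correlation of the
# cleaned ROI series, Fisher r-to-z, and proportional (sparsity)
# thresholding of the positive edges into weighted undirected networks.

#' ROI-by-ROI Pearson correlation matrix
#'
#' @param ts A [subject_timeseries()] object with at least 3 volumes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "netmed_ts"))
  if (nrow(ts$data) < 3) stop("need at least 3 volumes", call. = FALSE)
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(ts$roi_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(ts$data)
  (r + t(r)) / 2
}

#' Fisher r-to-z connectivity matrix
#'
#' Applies the variance-stabilising transform z = atanh(r) to every
#' off-diagonal entry, clamping |r| at `clip` so perfect correlations stay
#' finite, and zeroes the diagonal.
#'
#' @param r Correlation matrix (entries in [-1, 1]).
#' @param subject_id Identifier carried on the result.
#' @param roi_names ROI labels (defaults to `rownames(r)`).
#' @param clip Clamp for |r| before atanh.
#' @return An object of class `netmed_conn` with fields `subject_id`, `z`
#'   (symmetric, zero diagonal) and `roi_names`.
#' @export
#' @examples
#' fisher_z(diag(3))$z          # all zero
#' atanh(0.5)                   # 0.5493, the z for r = 0.5
fisher_z <- function(r, subject_id = "subject", roi_names = rownames(r),
                     clip = 0.999999) {
  assert_matrix(r, "r")
  stopifnot(nrow(r) == ncol(r), max(abs(r)) <= 1 + 1e-12)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(r)))
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(roi_names, roi_names)
  structure(
    list(subject_id = as.character(subject_id), z = z, roi_names = roi_names),
    class = "netmed_conn"
  )
}

#' @export
print.netmed_conn <- function(x, ...) {
  cat(sprintf("<netmed_conn> subject %s: %d x %d Fisher-z matrix\n",
              x$subject_id, nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Threshold a connectivity matrix at a sparsity level
#'
#' Keeps the `k = round(sparsity * n(n-1)/2)` largest strictly positive
#' off-diagonal z values (rounding half away from zero), zeroes everything
#' else, and symmetrises. Retained weights are the original z values —
#' networks stay weighted, never binarised. Negative edges never count
#' toward `k`. Ties at the cut weight are broken by ascending (row, column)
#' index for reproducibility. If fewer than `k` positive edges exist, all
#' positive edges are kept with a warning.
#'
#' @param cm A `netmed_conn` object from [fisher_z()].
#' @param sparsity Fraction of possible edges to retain, in (0, 1].
#' @return An object of class `netmed_network`: `sparsity`, `weights`
#'   (non-negative symmetric matrix), `n` (node count), `retained_edges`.
#' @export
threshold_by_sparsity <- function(cm, sparsity) {
  stopifnot(inherits(cm, "netmed_conn"), sparsity > 0, sparsity <= 1)
  n <- nrow(cm$z)
  k <- as.integer(round_half_up(sparsity * n * (n - 1) / 2))
  ut <- which(upper.tri(cm$z), arr.ind = TRUE)
  w <- cm$z[ut]
  pos <- which(w > 0)
  if (length(pos) < k) {
    warning(sprintf(
      "subject %s: only %d positive edges available for k = %d at sparsity %.2f; keeping all",
      cm$subject_id, length(pos), k, sparsity), call. = FALSE)
    k <- length(pos)
  }
  ord <- pos[order(-w[pos], ut[pos, 1], ut[pos, 2])]
  keep <- ord[seq_len(k)]
  weights <- matrix(0, n, n, dimnames = dimnames(cm$z))
  weights[ut[keep, , drop = FALSE]] <- w[keep]
  weights <- weights + t(weights)
  structure(
    list(sparsity = sparsity, weights = weights, n = n,
         retained_edges = k, subject_id = cm$subject_id,
         roi_names = cm$roi_names),
    class = "netmed_network"
  )
}

#' Sparsity sweep
#'
#' Thresholds one connectivity matrix at each sparsity level. The default
#' grid runs from 0.05 to 0.50 in steps of 0.05 (10 levels); because each
#' level keeps the top-k positive edges of the same ranking, the edge sets
#' are nested across the sweep.
#'
#' @param cm A `netmed_conn` object.
#' @param thresholds Strictly increasing sparsity levels in (0, 1].
#' @return A list of `netmed_network` objects, one per threshold.
#' @export
sparsity_sweep <- function(cm, thresholds = seq(0.05, 0.50, by = 0.05)) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0), all(thresholds <= 1),
            !is.unsorted(thresholds, strictly = TRUE))
  lapply(thresholds, function(s) threshold_by_sparsity(cm, s))
}
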