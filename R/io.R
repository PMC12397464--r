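# Plain-text file interchange: one TSV per subject for time series and
# connectivity matrices, whitespace-delimited 6-column motion files
# (realignment-parameter dialect), TSV phenotype/atlas tables, JSON for
# manifests and the synthetic ground truth.

#' Write a synthetic cohort to a directory
#'
#' Lays out the directory the pipeline reads back: `timeseries/<id>.tsv`
#' (volumes x ROIs with a ROI-name header), `motion/<id>.txt` (whitespace
#' 6-column, rotations in radians), `tissue/<id>.tsv` (wm, csf, global),
#' `phenotypes.tsv`, `atlas.tsv`, and `truth.json` recording the planted
#' parameters and seed.
#'
#' @param cohort A `netmed_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "netmed_cohort"))
  for (sub in c("timeseries", "motion", "tissue")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(cohort$timeseries)) {
    ts <- cohort$timeseries[[i]]
    readr::write_tsv(tibble::as_tibble(ts$data),
                     file.path(dir, "timeseries", paste0(ts$subject_id, ".tsv")))
    utils::write.table(cohort$confounds[[i]]$motion6,
                       file.path(dir, "motion", paste0(ts$subject_id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
    readr::write_tsv(tibble::as_tibble(cohort$confounds[[i]]$tissue_signals),
                     file.path(dir, "tissue", paste0(ts$subject_id, ".tsv")))
  }
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(cohort$atlas, file.path(dir, "atlas.tsv"))
  truth <- cohort$truth
  truth$covariate_effects <- as.list(truth$covariate_effects)
  truth$noise_sds <- as.list(truth$noise_sds)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Reads the layout written by [write_cohort()] back into a `netmed_cohort`
#' (without ground truth unless `truth.json` is present).
#'
#' @param dir Cohort directory.
#' @param tr_seconds Repetition time for the time series.
#' @return A `netmed_cohort` object.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  phen <- readr::read_tsv(file.path(dir, "phenotypes.tsv"),
                          show_col_types = FALSE)
  atlas <- readr::read_tsv(file.path(dir, "atlas.tsv"), show_col_types = FALSE)
  ids <- phen$subject_id
  timeseries <- lapply(ids, function(id) {
    d <- as.matrix(readr::read_tsv(
      file.path(dir, "timeseries", paste0(id, ".tsv")), show_col_types = FALSE))
    subject_timeseries(d, subject_id = id, tr_seconds = tr_seconds)
  })
  confounds <- lapply(ids, function(id) {
    m <- as.matrix(utils::read.table(file.path(dir, "motion", paste0(id, ".txt"))))
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    tissue_path <- file.path(dir, "tissue", paste0(id, ".tsv"))
    tissue <- if (file.exists(tissue_path)) {
      as.matrix(readr::read_tsv(tissue_path, show_col_types = FALSE))
    } else NULL
    structure(list(motion6 = m, tissue_signals = tissue),
              class = "netmed_confounds")
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    tr$covariate_effects <- unlist(tr$covariate_effects)
    tr$noise_sds <- unlist(tr$noise_sds)
    structure(tr, class = "netmed_truth")
  } else NULL
  structure(
    list(timeseries = timeseries, confounds = confounds, phenotypes = phen,
         truth = truth, atlas = atlas),
    class = "netmed_cohort"
  )
}

#' Validate a cohort's inputs for consistency
#'
#' Report-only checks: ROI column counts against the atlas, motion/volume
#' row alignment, missing phenotype fields, and id matching across sources.
#'
#' @param cohort A `netmed_cohort`.
#' @return A tibble with columns `subject_id` and `issue`; zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(cohort) {
  issues <- list()
  note <- function(id, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(subject_id = id, issue = msg)
  }
  n_atlas <- nrow(cohort$atlas)
  ts_ids <- vapply(cohort$timeseries, function(t) t$subject_id, character(1))
  for (i in seq_along(cohort$timeseries)) {
    ts <- cohort$timeseries[[i]]
    if (ncol(ts$data) != n_atlas) {
      note(ts$subject_id, sprintf("time series has %d columns but atlas has %d ROIs",
                                  ncol(ts$data), n_atlas))
    }
    cf <- cohort$confounds[[i]]
    if (!is.null(cf) && nrow(cf$motion6) != nrow(ts$data)) {
      note(ts$subject_id, sprintf("motion has %d rows but time series has %d volumes",
                                  nrow(cf$motion6), nrow(ts$data)))
    }
  }
  phen <- cohort$phenotypes
  for (id in setdiff(phen$subject_id, ts_ids)) {
    note(id, "subject in phenotypes but has no time series")
  }
  for (id in setdiff(ts_ids, phen$subject_id)) {
    note(id, "subject has time series but no phenotype row")
  }
  needed <- c("age", "sex", "education", "resilience", "speed")
  have <- intersect(needed, names(phen))
  if (length(have) < length(needed)) {
    note(NA_character_, paste("phenotype table lacks columns:",
                              paste(setdiff(needed, have), collapse = ", ")))
  } else {
    bad <- phen$subject_id[!stats::complete.cases(phen[, have])]
    for (id in bad) note(id, "missing phenotype fields")
  }
  if (length(issues) == 0) {
    tibble::tibble(subject_id = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
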