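# Orchestration of the full chain: QC -> cleaning -> networks -> metrics ->
# association screen (with optional permutation validation) -> mediation
# suite, with a JSON run manifest. All randomness fans out from one master
# seed through stable stage-specific derivations.

#' Default run configuration
#'
#' All thresholds and sizes are pre-filled with the study defaults: discard
#' 5 volumes, FD scrub threshold 0.5 mm, band-pass 0.01-0.1 Hz, sparsity
#' 0.05-0.50 in steps of 0.05, four bilateral target regions, covariates
#' age/sex/education, B = 5000 permutations and 5000 bootstrap resamples.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `netmed_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_discard = 5L,
    fd_threshold_mm = 0.5,
    low_hz = 0.01, high_hz = 0.1,
    motion_rule = "conjunction",
    thresholds = seq(0.05, 0.50, by = 0.05),
    metrics = "degree",
    target_regions = c("Thalamus", "Hippocampus", "Caudate", "Insula"),
    covariates = c("age", "sex", "education"),
    outcomes = c("speed", "resilience"),
    mediation_x = "resilience", mediation_y = "speed",
    include_education_mediator = TRUE,
    B = 5000L, n_boot = 5000L,
    standardize = TRUE,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "netmed_config")
}

#' Run the full study pipeline on a cohort
#'
#' Executes every stage on an in-memory cohort (from [simulate_cohort()] or
#' [read_cohort()]): per-subject cleaning and QC, Fisher-z network
#' construction, sparsity-averaged nodal metrics, bilateral collapsing,
#' covariate-adjusted association screens for each configured outcome
#' (with permutation validation when `config$B > 0`), and the mediation
#' suite. With an empty `target_regions` the association and mediation
#' stages are skipped.
#'
#' @param cohort A `netmed_cohort`.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a `manifest.json`.
#' @param permutations If `TRUE`, adds permutation empirical p-values to the
#'   association screens (B taken from the config).
#' @return A list of class `netmed_study`: `qc`, `roi_metrics`,
#'   `region_metrics`, `associations` (one `netmed_screen` per outcome),
#'   `mediation`, `manifest`.
#' @export
run_study <- function(cohort, config = run_config(), out_dir = NULL,
                      permutations = FALSE) {
  stopifnot(inherits(cohort, "netmed_cohort"), inherits(config, "netmed_config"))
  t0 <- Sys.time()
  issues <- validate_inputs(cohort)
  if (nrow(issues) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("  %s: %s", issues$subject_id, issues$issue), collapse = "\n"),
         call. = FALSE)
  }

  # per-subject cleaning + QC evidence
  cleaned <- vector("list", length(cohort$timeseries))
  qc_rows <- vector("list", length(cohort$timeseries))
  for (i in seq_along(cohort$timeseries)) {
    cl <- clean_timeseries(cohort$timeseries[[i]], cohort$confounds[[i]],
                           n_discard = config$n_discard,
                           fd_threshold_mm = config$fd_threshold_mm,
                           low_hz = config$low_hz, high_hz = config$high_hz)
    cleaned[[i]] <- cl$ts
    ph <- cohort$phenotypes[cohort$phenotypes$subject_id == cl$ts$subject_id, ]
    qc_rows[[i]] <- tibble::tibble(
      subject_id = cl$ts$subject_id,
      max_abs_translation_mm = cl$max_abs_translation_mm,
      max_abs_rotation_deg = cl$max_abs_rotation_deg,
      mean_fd = cl$mean_fd,
      n_scrubbed = cl$n_scrubbed,
      moca = if ("moca" %in% names(ph)) ph$moca[1] else NA_integer_,
      gds = if ("gds" %in% names(ph)) ph$gds[1] else NA_integer_
    )
  }
  qc <- qc_filter(dplyr::bind_rows(qc_rows), motion_rule = config$motion_rule)
  included <- qc$subject_id[qc$included]
  cleaned <- cleaned[vapply(cleaned, function(t) t$subject_id, character(1)) %in% included]

  # networks and threshold-averaged nodal metrics
  roi_metrics <- purrr::map_dfr(cleaned, function(ts) {
    cm <- fisher_z(correlation_matrix(ts), subject_id = ts$subject_id,
                   roi_names = ts$roi_names)
    nodal_metrics(cm, metrics = config$metrics, thresholds = config$thresholds)
  })

  associations <- list()
  med <- NULL
  reg_metrics <- NULL
  if (length(config$target_regions) > 0) {
    reg_metrics <- region_metrics(roi_metrics, cohort$atlas,
                                  regions = config$target_regions)
    phen <- cohort$phenotypes[cohort$phenotypes$subject_id %in% included, ]
    for (outc in config$outcomes) {
      associations[[outc]] <- roi_association_screen(
        reg_metrics, phen, outcome = outc,
        covariates = config$covariates, regions = config$target_regions,
        metric = config$metrics[1],
        B = if (permutations) config$B else 0L,
        seed = derive_seed(config$seed, paste0("screen-", outc))
      )
    }
    med <- run_mediation_suite(
      reg_metrics, phen, regions = config$target_regions,
      x = config$mediation_x, y = config$mediation_y,
      covariates = config$covariates, metric = config$metrics[1],
      include_education = config$include_education_mediator,
      n_boot = config$n_boot, standardize = config$standardize,
      seed = derive_seed(config$seed, "mediation")
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("netmed")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "thresholds")],
    thresholds = config$thresholds,
    n_subjects_input = length(cohort$timeseries),
    n_subjects_included = length(included),
    stages_skipped = if (length(config$target_regions) == 0) {
      c("association", "mediation")
    } else character()
  )

  study <- structure(
    list(qc = qc, roi_metrics = roi_metrics, region_metrics = reg_metrics,
         associations = associations, mediation = med, manifest = manifest),
    class = "netmed_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.netmed_study <- function(x, ...) {
  cat(sprintf("<netmed_study> %d/%d subjects included\n",
              x$manifest$n_subjects_included, x$manifest$n_subjects_input))
  for (nm in names(x$associations)) {
    cat(sprintf("  association screen [%s]:\n", nm))
    print(as.data.frame(x$associations[[nm]][, c("region", "n", "rho", "p", "q")]),
          digits = 3, row.names = FALSE)
  }
  if (!is.null(x$mediation)) {
    cat("  mediation suite:\n")
    print(as.data.frame(
      x$mediation[, c("mediator", "a", "b", "c_prime", "indirect",
                      "ci_low", "ci_high", "significant")]),
      digits = 3, row.names = FALSE)
  }
  invisible(x)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$qc, file.path(out_dir, "qc.tsv"))
  readr::write_tsv(study$roi_metrics, file.path(out_dir, "roi_metrics.tsv"))
  if (!is.null(study$region_metrics)) {
    readr::write_tsv(study$region_metrics, file.path(out_dir, "region_metrics.tsv"))
  }
  for (nm in names(study$associations)) {
    readr::write_tsv(study$associations[[nm]],
                     file.path(out_dir, paste0("associations_", nm, ".tsv")))
  }
  if (!is.null(study$mediation)) {
    readr::write_tsv(dplyr::select(study$mediation, -"fit"),
                     file.path(out_dir, "mediation.tsv"))
  }
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
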