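# Weighted nodal graph metrics on thresholded networks, averaged across the
# sparsity sweep, with bilateral (left/right homologue) collapsing for the
# regions of interest. Distances for the shortest-path metrics use the
# standard reciprocal-weight edge length 1/x_ij; unreachable pairs
# contribute 0 to efficiency and no paths to betweenness.

#' Weighted degree centrality
#'
#' dc(i) = sum over j != i of x_ij: the total weight of edges incident to
#' each node (connection strength, not edge count).
#'
#' @param net A `netmed_network` from [threshold_by_sparsity()].
#' @return Named numeric vector, one value per node.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "netmed_network"))
  rowSums(net$weights)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted nodal efficiency
#'
#' eff(i) = (1/(n-1)) * sum over j != i of 1/d(i, j), where d is the
#' shortest-path distance under edge length 1/x_ij. Pairs in different
#' components contribute 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector in [0, max inverse-distance bound].
#' @export
nodal_efficiency <- function(net) {
  stopifnot(inherits(net, "netmed_network"))
  n <- net$n
  if (n < 2) return(stats::setNames(numeric(n), rownames(net$weights)))
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(numeric(n), rownames(net$weights)))
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  stats::setNames(rowSums(inv) / (n - 1), rownames(net$weights))
}

#' Weighted betweenness centrality
#'
#' The number of shortest paths between other node pairs that pass through
#' each node, with equal-length multiplicities split fractionally
#' (unnormalised convention), under edge length 1/x_ij.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "netmed_network"))
  if (net$n < 3) return(stats::setNames(numeric(net$n), rownames(net$weights)))
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(numeric(net$n), rownames(net$weights)))
  }
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = 1 / igraph::E(g)$weight)
  stats::setNames(as.numeric(b), rownames(net$weights))
}

#' Average metric vectors across sparsity thresholds
#'
#' Unweighted arithmetic mean per node of the per-threshold metric vectors,
#' the robustness device that frees results from any single threshold
#' choice.
#'
#' @param vectors A list of equal-length numeric vectors (one per
#'   threshold).
#' @return A numeric vector of per-node means.
#' @export
average_across_thresholds <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("metric vectors have mismatched lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  Reduce(`+`, vectors) / length(vectors)
}

#' Bilateral (left/right) average of a nodal metric
#'
#' Collapses the two hemisphere values of a paired region into one:
#' (value_L + value_R) / 2.
#'
#' @param values Per-ROI numeric vector ordered as the atlas indices.
#' @param atlas Atlas label table (see [default_atlas()]).
#' @param region Region name with an L/R pair in the atlas.
#' @return A single numeric value.
#' @export
bilateral_average <- function(values, atlas, region) {
  idx <- region_indices(atlas, region)
  mean(values[idx])
}

metric_fun <- function(metric) {
  switch(metric,
    degree = degree_centrality,
    nodal_efficiency = nodal_efficiency,
    betweenness = betweenness_centrality,
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  )
}

#' Threshold-averaged nodal metrics for one subject
#'
#' Runs the sparsity sweep on a connectivity matrix, computes each requested
#' metric on every thresholded network, and averages across thresholds.
#'
#' @param cm A `netmed_conn` object.
#' @param metrics Metrics to compute, among `"degree"`,
#'   `"nodal_efficiency"`, `"betweenness"`.
#' @param thresholds Sparsity grid passed to [sparsity_sweep()].
#' @return A tibble with columns `subject_id`, `metric`, `roi`, `value`.
#' @export
nodal_metrics <- function(cm, metrics = "degree",
                          thresholds = seq(0.05, 0.50, by = 0.05)) {
  stopifnot(inherits(cm, "netmed_conn"))
  nets <- sparsity_sweep(cm, thresholds)
  purrr::map_dfr(metrics, function(m) {
    f <- metric_fun(m)
    avg <- average_across_thresholds(lapply(nets, f))
    tibble::tibble(subject_id = cm$subject_id, metric = m,
                   roi = cm$roi_names, value = as.numeric(avg))
  })
}

#' Bilateral region metrics for a cohort metric table
#'
#' Collapses a per-ROI metric table (long format, as returned by
#' [nodal_metrics()] over subjects) to per-region values by averaging the
#' left and right homologue of each requested region.
#'
#' @param metric_tbl Tibble with columns `subject_id`, `metric`, `roi`,
#'   `value`.
#' @param atlas Atlas label table.
#' @param regions Region names to collapse (each must have an L/R pair).
#' @return A tibble with columns `subject_id`, `metric`, `region`, `value`.
#' @export
region_metrics <- function(metric_tbl, atlas,
                           regions = c("Thalamus", "Hippocampus",
                                       "Caudate", "Insula")) {
  stopifnot(all(c("subject_id", "metric", "roi", "value") %in% names(metric_tbl)))
  pairs <- purrr::map_dfr(regions, function(rg) {
    idx <- region_indices(atlas, rg)
    tibble::tibble(region = rg, roi = atlas$name[match(idx, atlas$index)])
  })
  metric_tbl |>
    dplyr::inner_join(pairs, by = "roi") |>
    dplyr::group_by(.data$subject_id, .data$metric, .data$region) |>
    dplyr::summarise(value = mean(.data$value), n_rois = dplyr::n(),
                     .groups = "drop") |>
    (\(d) {
      bad <- d$n_rois != 2L
      if (any(bad)) {
        stop("region(s) without exactly one L and one R value: ",
             paste(unique(d$region[bad]), collapse = ", "), call. = FALSE)
      }
      dplyr::select(d, -"n_rois")
    })()
}
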